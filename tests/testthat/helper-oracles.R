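# Independent brute-force reference implementations (plain loops, no shared
# code with the package) plus small fixture builders.

bf_silhouette <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  labels <- as.integer(factor(labels))
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      members <- which(labels == cl)
      b <- min(b, mean(vapply(members, function(j) d(i, j), numeric(1))))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

bf_hubert_gamma <- function(dmat, labels) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  dv <- c()
  iv <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dv <- c(dv, dmat[i, j])
      iv <- c(iv, as.numeric(labels[i] != labels[j]))
    }
  }
  cor(dv, iv)
}

bf_l_method <- function(x, y) {
  n <- length(x)
  best <- NULL
  best_err <- Inf
  for (ci in 2:(n - 2)) {
    xl <- x[1:ci]; yl <- y[1:ci]
    xr <- x[(ci + 1):n]; yr <- y[(ci + 1):n]
    rl <- residuals(lm(yl ~ xl))
    rr <- residuals(lm(yr ~ xr))
    err <- (ci * sqrt(mean(rl^2)) + (n - ci) * sqrt(mean(rr^2))) / n
    if (err < best_err - 1e-12) {
      best_err <- err
      best <- x[ci]
    }
  }
  best
}

# Kinematic record rows with exactly consistent ratio descriptors.
make_kin_df <- function(vcl, lin, wob, alh = 2, bcf = 5,
                        sample_type = "fresh", medium = "CAP", time_min = 15) {
  n <- length(vcl)
  lin <- rep_len(lin, n); wob <- rep_len(wob, n)
  alh <- rep_len(alh, n); bcf <- rep_len(bcf, n)
  vsl <- lin * vcl / 100
  vap <- wob * vcl / 100
  data.frame(VCL = vcl, VSL = vsl, VAP = vap, LIN = lin,
             STR = 100 * vsl / vap, WOB = wob, ALH = alh, BCF = bcf,
             sample_type = sample_type, medium = medium, time_min = time_min,
             replicate_id = "R1", sperm_id = sprintf("s%04d", seq_len(n)))
}

# Gaussian blob matrix for clustering tests.
make_blobs <- function(k, n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per), 2,
          centers[i, ], "+")
  }))
}

default_scn <- function(...) suppressWarnings(synthetic_scenario(...))
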