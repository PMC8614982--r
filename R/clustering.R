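#' Configuration for the two-step subpopulation clustering
#'
#' @param driver_vars kinematic variables driving the classification
#'   (default VCL, LIN, ALH, BCF).
#' @param k_range_step1 candidate cluster counts scanned in the k-means step
#'   (default 10..25). The non-hierarchical step is a compression device:
#'   it must over-partition so the hierarchical step has centroids to
#'   agglomerate, so the floor defaults to max(final_k_range) + 2; a floor
#'   at or below the true cluster count collapses the second step.
#' @param n_restarts k-means restarts per candidate k (k-means++ seeding,
#'   Lloyd iterations; best of restarts by within-cluster sum of squares).
#' @param linkage agglomeration rule for merging step-1 centroids: "ward"
#'   (Ward on Euclidean distances, the default), "average" or "complete".
#' @param final_k_range candidate final subpopulation counts (default 2..8).
#' @param n_folds subsamples for the stability ensemble (default 10).
#' @param n_sil silhouette evaluation is restricted to at most this many
#'   points (seeded subsample) to keep the O(n^2) distance matrix tractable.
#' @param reconcile which criterion wins when the Hubert Gamma argmax and the
#'   L-method knee of the merge-height curve disagree: "lmethod" (default)
#'   or "gamma". The knee criterion is the robust one when adjacent clusters
#'   overlap mildly (Gamma's argmax then drifts one below the true count);
#'   both candidates are always recorded in the diagnostics, and Gamma
#'   decides whenever the tree is too small for a knee fit.
#' @return A list of class `clustering_config`.
#' @export
clustering_config <- function(driver_vars = c("VCL", "LIN", "ALH", "BCF"),
                              k_range_step1 = 10:25,
                              n_restarts = 20,
                              linkage = c("ward", "average", "complete"),
                              final_k_range = 2:8,
                              n_folds = 10,
                              n_sil = 2000,
                              reconcile = c("lmethod", "gamma")) {
  linkage <- match.arg(linkage)
  reconcile <- match.arg(reconcile)
  stopifnot(length(driver_vars) >= 1, all(k_range_step1 >= 2),
            n_restarts >= 1, all(final_k_range >= 2), n_folds >= 2,
            n_sil >= 10)
  structure(list(driver_vars = driver_vars,
                 k_range_step1 = sort(unique(as.integer(k_range_step1))),
                 n_restarts = as.integer(n_restarts),
                 linkage = linkage,
                 final_k_range = sort(unique(as.integer(final_k_range))),
                 n_folds = as.integer(n_folds),
                 n_sil = as.integer(n_sil),
                 reconcile = reconcile),
            class = "clustering_config")
}

#' Center and scale a variable matrix
#'
#' Standardizes every column to mean 0 and (sample, n-1 denominator) standard
#' deviation 1, as required before distance-based clustering of variables
#' measured on different scales.
#'
#' @param x numeric matrix (observations x variables), >= 2 rows.
#' @return List with `scaled` (the standardized matrix), `center` and `scale`
#'   (per-variable mean and sd), class `standardization_params`.
#' @export
standardize_kinematics <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  }
  scaled <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  structure(list(scaled = scaled, center = ctr, scale = scl),
            class = "standardization_params")
}

## Apply fitted standardization parameters to new data.
apply_standardization <- function(params, x) {
  sweep(sweep(as.matrix(x), 2, params$center), 2, params$scale, "/")
}

## k-means++ seeding: spread initial centers with probability proportional to
## squared distance from the nearest already-chosen center.
kmeans_pp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ])^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      idx[j + 1L] <- sample.int(n, 1)
    } else {
      idx[j + 1L] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j + 1L], ])^2))
  }
  x[idx, , drop = FALSE]
}

#' Step-1 k-means partition
#'
#' Lloyd iterations from k-means++ starts, best of `n_restarts` by total
#' within-cluster sum of squares (ties keep the earliest restart). Restarts
#' producing an empty cluster are re-seeded; if no restart succeeds, k is
#' reduced with a warning.
#'
#' @param x numeric matrix (standardized driver variables).
#' @param k number of clusters (k <= rows).
#' @param n_restarts number of seeded restarts.
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the partition is a pure function of (x, k, n_restarts, seed).
#' @return List with `centers`, `cluster`, `tot_withinss`, `k`.
#' @export
kmeans_step1 <- function(x, k, n_restarts = 20, seed = NULL) {
  x <- as.matrix(x)
  stopifnot(k >= 1, k <= nrow(x))
  if (!is.null(seed)) set.seed(seed)
  repeat {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- NULL
      for (attempt in 1:5) {
        centers0 <- kmeans_pp_centers(x, k)
        fit <- tryCatch(
          withCallingHandlers(
            stats::kmeans(x, centers = centers0, iter.max = 100,
                          algorithm = "Lloyd"),
            warning = function(w) invokeRestart("muffleWarning")),
          error = function(e) NULL)
        if (!is.null(fit)) break
      }
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (!is.null(best)) {
      return(list(centers = best$centers, cluster = best$cluster,
                  tot_withinss = best$tot.withinss, k = k))
    }
    if (k <= 1L) stop("k-means failed even at k = 1")
    warning("persistent empty clusters at k = ", k, "; reducing to k = ", k - 1L)
    k <- k - 1L
  }
}

#' Select the step-1 cluster count by silhouette average width
#'
#' Scans `k_range_step1`, fitting k-means at every k and scoring each
#' partition by the silhouette average width computed on a fixed seeded
#' subsample of at most `n_sil` points (one distance matrix, reused across
#' k). Ties go to the smallest k.
#'
#' @param x standardized driver-variable matrix.
#' @param config a [clustering_config].
#' @param seed optional integer seed for the scan (subsample + restarts).
#' @return List with `k` (the selected count), `fit` (its k-means partition)
#'   and `curve` (data.frame of k vs silhouette).
#' @export
select_k_step1 <- function(x, config = clustering_config(), seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is.null(seed)) set.seed(seed)
  sub <- if (n > config$n_sil) sort(sample.int(n, config$n_sil)) else seq_len(n)
  dmat <- as.matrix(stats::dist(x[sub, , drop = FALSE]))

  kvals <- config$k_range_step1[config$k_range_step1 < n]
  if (length(kvals) == 0L) stop("k_range_step1 incompatible with n = ", n)
  best <- NULL
  curve <- data.frame(k = kvals, silhouette = NA_real_)
  for (i in seq_along(kvals)) {
    km <- kmeans_step1(x, kvals[i], n_restarts = config$n_restarts)
    sil <- if (length(unique(km$cluster[sub])) >= 2L) {
      silhouette_avg_width(labels = km$cluster[sub], dmat = dmat)
    } else NA_real_
    curve$silhouette[i] <- sil
    if (!is.na(sil) && (is.null(best) || sil > best$sil)) {
      best <- list(k = km$k, fit = km, sil = sil)
    }
  }
  if (is.null(best)) stop("silhouette undefined for every candidate k")
  list(k = best$k, fit = best$fit, curve = curve)
}

#' Agglomerate step-1 centroids into a dendrogram
#'
#' @param centroids matrix of step-1 centroids in standardized space.
#' @param linkage "ward" (Ward criterion on Euclidean distances, via
#'   `hclust(method = "ward.D2")`; the merge height of two singletons equals
#'   their Euclidean distance), "average" or "complete".
#' @return An `hclust` merge tree.
#' @export
hierarchical_merge <- function(centroids, linkage = "ward") {
  stopifnot(nrow(centroids) >= 2)
  method <- switch(linkage, ward = "ward.D2", average = "average",
                   complete = "complete",
                   stop("unknown linkage: ", linkage))
  stats::hclust(stats::dist(centroids), method = method)
}

#' Select the final subpopulation count from the centroid dendrogram
#'
#' Computes the Hubert Gamma coefficient of every cut of the dendrogram over
#' `final_k_range` (candidate A = argmax, ties to the smallest k) and the
#' L-method knee of the merge-height-versus-cluster-count curve (candidate
#' B). When they agree that count is returned; otherwise the criterion named
#' in `config$reconcile` wins and the disagreement is recorded.
#'
#' @param dend `hclust` tree over the step-1 centroids.
#' @param dmat distance matrix: among the step-1 centroids when
#'   `step1_labels` is `NULL`, otherwise among the (sub)sampled records whose
#'   step-1 cluster indices are given in `step1_labels`. Evaluating Gamma at
#'   record level weights each centroid by its cluster size and allows the
#'   final count to equal the step-1 count.
#' @param config a [clustering_config].
#' @param step1_labels optional integer vector of step-1 cluster indices,
#'   one per row of `dmat`.
#' @return List with `final_k`, `candidate_gamma`, `candidate_lmethod`,
#'   `gamma_curve`, `height_curve`, `agreement`.
#' @export
select_final_k <- function(dend, dmat, config = clustering_config(),
                           step1_labels = NULL) {
  n_c <- length(dend$order)
  k_cap <- if (is.null(step1_labels)) n_c - 1L else n_c
  kvals <- config$final_k_range[config$final_k_range <= k_cap]
  if (length(kvals) == 0L) stop("final_k_range incompatible with ", n_c, " centroids")

  gamma <- vapply(kvals, function(k) {
    cut_k <- stats::cutree(dend, k)
    part <- if (is.null(step1_labels)) cut_k else cut_k[step1_labels]
    tryCatch(hubert_gamma(dmat, part), error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(gamma))) stop("Hubert Gamma undefined over the whole final_k_range")
  cand_a <- kvals[which.max(gamma)]

  ## merge-height curve: y(k) = height of the merge that forms k clusters
  hk <- 2:(n_c - 1L)
  height_curve <- data.frame(k = hk, height = rev(dend$height)[hk - 1L])
  cand_b <- if (nrow(height_curve) >= 4L) {
    l_method_knee(height_curve$k, height_curve$height)
  } else NA_integer_
  ## a knee at the boundary of the admissible breakpoints is not identified
  ## (the steep segment may continue beyond the range): only Gamma decides
  if (!is.na(cand_b) &&
      (cand_b == height_curve$k[2] ||
         cand_b == height_curve$k[nrow(height_curve) - 2L])) {
    cand_b <- NA_integer_
  }

  agreement <- !is.na(cand_b) && cand_a == cand_b
  final_k <- if (agreement || is.na(cand_b)) {
    cand_a
  } else if (config$reconcile == "lmethod") cand_b else cand_a
  if (!agreement && !is.na(cand_b)) {
    message("final-k criteria disagree: Gamma -> ", cand_a,
            ", L-method -> ", cand_b, "; using ", final_k)
  }
  list(final_k = as.integer(final_k),
       candidate_gamma = as.integer(cand_a),
       candidate_lmethod = as.integer(cand_b),
       gamma_curve = data.frame(k = kvals, gamma = gamma),
       height_curve = height_curve,
       agreement = agreement)
}

#' Canonical subpopulation labels
#'
#' Orders clusters by ascending mean (unstandardized) VCL of their member
#' records, ALH breaking ties, and relabels them SP1..SPk. SP1 is therefore
#' always the slowest subpopulation and SPk the fastest, so labels are
#' comparable across independent runs.
#'
#' @param labels cluster labels, one per record.
#' @param records data.frame with at least `VCL` and `ALH` columns, same row
#'   order as `labels`.
#' @return List with `assignment` (factor with levels SP1..SPk) and `map`
#'   (named vector: original label -> canonical label).
#' @export
canonicalize_labels <- function(labels, records) {
  labels <- as.character(labels)
  vcl <- tapply(records$VCL, labels, mean)
  alh <- tapply(records$ALH, labels, mean)
  ord <- order(vcl, alh)
  canon <- paste0("SP", seq_along(ord))
  map <- stats::setNames(canon, names(vcl)[ord])
  assignment <- factor(unname(map[labels]), levels = canon)
  list(assignment = assignment, map = map)
}

#' Fit the two-step subpopulation model
#'
#' The full classification of one dataset: standardize the driver variables,
#' select the step-1 k-means partition by silhouette average width,
#' agglomerate the step-1 centroids hierarchically, cut the tree at the count
#' chosen by Hubert Gamma and the L-method, and relabel the final clusters
#' canonically by ascending VCL.
#'
#' @param ds a [kinematic_dataset] of motile records.
#' @param config a [clustering_config].
#' @param seed integer seed making the whole fit deterministic.
#' @return An object of class `subpopulation_model`.
#' @export
fit_subpopulations <- function(ds, config = clustering_config(), seed = 1) {
  rec <- as.data.frame(ds)
  missing_vars <- setdiff(config$driver_vars, names(rec))
  if (length(missing_vars) > 0L) stop("driver variables absent: ",
                                      paste(missing_vars, collapse = ", "))
  std <- standardize_kinematics(as.matrix(rec[, config$driver_vars]))

  set.seed(seed)
  sel <- select_k_step1(std$scaled, config)
  dend <- hierarchical_merge(sel$fit$centers, config$linkage)
  n <- nrow(std$scaled)
  sub <- if (n > config$n_sil) sort(sample.int(n, config$n_sil)) else seq_len(n)
  fin <- select_final_k(dend,
                        stats::dist(std$scaled[sub, , drop = FALSE]),
                        config, step1_labels = sel$fit$cluster[sub])
  merged <- stats::cutree(dend, fin$final_k)
  raw <- merged[sel$fit$cluster]
  canon <- canonicalize_labels(raw, rec)

  centroids <- do.call(rbind, lapply(levels(canon$assignment), function(sp) {
    colMeans(rec[canon$assignment == sp, KINEMATIC_VARS, drop = FALSE])
  }))
  rownames(centroids) <- levels(canon$assignment)

  structure(list(
    step1_k = sel$k,
    step1_centroids = sel$fit$centers,
    dendrogram = dend,
    final_k = fin$final_k,
    assignment = canon$assignment,
    centroids = centroids,
    diagnostics = list(silhouette_curve = sel$curve,
                       gamma_curve = fin$gamma_curve,
                       height_curve = fin$height_curve,
                       candidate_gamma = fin$candidate_gamma,
                       candidate_lmethod = fin$candidate_lmethod,
                       agreement = fin$agreement),
    standardization = std[c("center", "scale")],
    config = config,
    seed = seed,
    n = nrow(rec)), class = "subpopulation_model")
}

#' @export
print.subpopulation_model <- function(x, ...) {
  cat("<subpopulation_model> n =", x$n, "| step-1 k =", x$step1_k,
      "| final k =", x$final_k, "\n")
  print(round(x$centroids, 2))
  invisible(x)
}

#' Per-condition subpopulation proportions
#'
#' @param assignment factor of canonical SP labels, one per record.
#' @param records data.frame with `sample_type`, `medium`, `time_min`.
#' @return Long data.frame (sample_type, medium, time_min, SP, proportion,
#'   n); proportions sum to 1 within each condition.
#' @export
sp_proportions <- function(assignment, records) {
  cond <- interaction(records$sample_type, records$medium, records$time_min,
                      drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(levels(cond), function(cl) {
    idx <- cond == cl
    parts <- strsplit(cl, "\r", fixed = TRUE)[[1]]
    tab <- table(assignment[idx])
    data.frame(sample_type = parts[1], medium = parts[2],
               time_min = as.numeric(parts[3]),
               SP = names(tab),
               proportion = as.numeric(tab) / sum(tab),
               n = sum(idx), row.names = NULL)
  }))
  out[order(out$sample_type, out$medium, out$time_min, out$SP), ]
}

#' Ten-fold subsample stability ensemble
#'
#' Randomly splits the records into `n_folds` subsamples and repeats the full
#' two-step classification `n_folds` times, each run excluding exactly one
#' subsample. Per-condition subpopulation proportions are computed on each
#' run's included records; the summary reports their mean and standard
#' deviation across runs (over the runs in which a condition was present).
#' Standardization is refitted inside every run, so each run is an
#' independent analysis of its 9/10 of the data.
#'
#' @param ds a [kinematic_dataset] of motile records.
#' @param config a [clustering_config].
#' @param seed integer seed (drives both the fold split and every run; runs
#'   share the seed, so two runs over identical records give identical fits).
#' @param folds optional integer vector (one entry per record, values in
#'   1..n_folds) overriding the random split, e.g. to encode a known
#'   replicate structure.
#' @return An object of class `subsample_ensemble`: `runs` (per fold: the
#'   fitted model and its proportion table), `summary` (mean/sd across runs),
#'   `folds`, `config`.
#' @export
tenfold_ensemble <- function(ds, config = clustering_config(), seed = 1,
                             folds = NULL) {
  rec <- as.data.frame(ds)
  n <- nrow(rec)
  set.seed(seed)
  if (is.null(folds)) {
    folds <- sample(rep_len(seq_len(config$n_folds), n))
  } else {
    stopifnot(length(folds) == n, all(folds %in% seq_len(config$n_folds)))
  }

  runs <- lapply(seq_len(config$n_folds), function(f) {
    keep <- folds != f
    sub <- ds
    sub$records <- rec[keep, , drop = FALSE]
    model <- fit_subpopulations(sub, config, seed = seed)
    props <- sp_proportions(model$assignment, sub$records)
    props$fold <- f
    list(fold = f, model = model, proportions = props)
  })

  all_props <- do.call(rbind, lapply(runs, `[[`, "proportions"))
  key <- interaction(all_props$sample_type, all_props$medium,
                     all_props$time_min, all_props$SP, drop = TRUE, sep = "\r")
  summary <- do.call(rbind, lapply(levels(key), function(kk) {
    v <- all_props$proportion[key == kk]
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
    data.frame(sample_type = parts[1], medium = parts[2],
               time_min = as.numeric(parts[3]), SP = parts[4],
               mean = mean(v), sd = stats::sd(v), n_runs = length(v),
               row.names = NULL)
  }))
  summary <- summary[order(summary$sample_type, summary$medium,
                           summary$time_min, summary$SP), ]
  structure(list(runs = runs, summary = summary, folds = folds,
                 config = config, seed = seed),
            class = "subsample_ensemble")
}

#' Summarize subpopulation kinematics across ensemble runs
#'
#' For every canonical subpopulation, the mean over runs of the per-run
#' member means of all eight kinematic variables, with the across-run
#' standard error (sd across runs / sqrt(number of runs)).
#'
#' @param ensemble a [tenfold_ensemble] result.
#' @return Data.frame with columns variable, SP, mean, sem, n_runs.
#' @export
summarize_subpopulations <- function(ensemble) {
  stopifnot(inherits(ensemble, "subsample_ensemble"))
  per_run <- do.call(rbind, lapply(ensemble$runs, function(r) {
    cent <- r$model$centroids
    data.frame(fold = r$fold, SP = rownames(cent), cent, row.names = NULL)
  }))
  sps <- sort(unique(per_run$SP))
  out <- do.call(rbind, lapply(KINEMATIC_VARS, function(v) {
    do.call(rbind, lapply(sps, function(sp) {
      vals <- per_run[per_run$SP == sp, v]
      data.frame(variable = v, SP = sp, mean = mean(vals),
                 sem = stats::sd(vals) / sqrt(length(vals)),
                 n_runs = length(vals), row.names = NULL)
    }))
  }))
  out
}

#' Select one representative variable per correlated group
#'
#' Variable-group analysis: hierarchically clusters the candidate variables
#' on the dissimilarity 1 - |Pearson r| (average linkage), cuts into
#' `n_groups` groups, and keeps from each group the variable with the
#' largest mean absolute correlation to the other members of its group
#' (singletons represent themselves). Constant variables are excluded with a
#' warning.
#'
#' @param ds a [kinematic_dataset] (>= 10 records).
#' @param candidates candidate variable names (>= 2).
#' @param n_groups number of variable groups to keep (default 4).
#' @return Character vector of selected variable names, in canonical order.
#' @export
variable_group_select <- function(ds, candidates = KINEMATIC_VARS, n_groups = 4) {
  rec <- as.data.frame(ds)
  stopifnot(length(candidates) >= 2, nrow(rec) >= 10)
  m <- as.matrix(rec[, candidates, drop = FALSE])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant variable(s): ",
            paste(candidates[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  vars <- colnames(m)
  if (length(vars) < 2L) stop("fewer than 2 usable candidate variables")
  cc <- stats::cor(m)
  hc <- stats::hclust(stats::as.dist(1 - abs(cc)), method = "average")
  groups <- stats::cutree(hc, k = min(n_groups, length(vars)))
  reps <- vapply(unique(groups), function(g) {
    members <- vars[groups == g]
    if (length(members) == 1L) return(members)
    within <- abs(cc[members, members, drop = FALSE])
    diag(within) <- NA
    members[which.max(rowMeans(within, na.rm = TRUE))]
  }, character(1))
  vars[vars %in% reps]
}
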