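## Time-course comparisons and the subpopulation/marker correlation table.
##
## A time-course table is long-format: one row per (sample_type, medium,
## time_min, replicate_id, endpoint, value). Endpoints used by the pipeline:
## sp1_prop..sp4_prop (subpopulation proportions), mito_activity (proportion
## of viable spermatozoa with active mitochondria), py_head, py_midpiece,
## py_principal, py_tail (baseline-normalized regional fluorescence).

#' Per-time means and all-pairs comparisons for one endpoint
#'
#' Fits a saturated one-way model with incubation time as a factor
#' (`value ~ 0 + factor(time_min)`), so the fitted values are exactly the
#' per-time means, and tests every pair of times with a Wald t contrast on
#' the residual variance. Pairwise p values are unadjusted by default (a
#' Holm correction is available via `adjust`), mirroring the all-pairs
#' letter displays such analyses report.
#'
#' @param tc long-format time-course data.frame.
#' @param endpoint endpoint name to model.
#' @param sample_type,medium condition selectors.
#' @param alpha significance level for the letter display (default 0.05).
#' @param adjust "none" (default) or any `p.adjust` method.
#' @return List with `means` (time_min, mean, n, letter), `p_matrix`
#'   (symmetric, times x times), `alpha`, `model`.
#' @export
fit_time_model <- function(tc, endpoint, sample_type, medium,
                           alpha = 0.05, adjust = "none") {
  sub <- tc[tc$endpoint == endpoint & tc$sample_type == sample_type &
              tc$medium == medium, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for endpoint ", endpoint)
  times <- sort(unique(sub$time_min))
  if (length(times) < 2L) stop("need at least 2 time levels")
  counts <- table(factor(sub$time_min, levels = times))
  if (any(counts < 2L)) {
    stop("fewer than 2 replicates at time(s) ",
         paste(times[counts < 2], collapse = ", "),
         ": no residual degrees of freedom for pairwise tests")
  }
  tf <- factor(sub$time_min, levels = times)
  fit <- stats::lm(sub$value ~ 0 + tf)
  mu <- stats::coef(fit)
  sigma2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  nn <- as.numeric(counts)

  nt <- length(times)
  scale <- max(abs(mu), 1)
  pmat <- matrix(1, nt, nt, dimnames = list(times, times))
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      se <- sqrt(sigma2 * (1 / nn[i] + 1 / nn[j]))
      diff <- mu[i] - mu[j]
      p <- if (se < 1e-10 * scale) {
        ## numerically zero residual variance: means are either identical
        ## (p = 1) or separated with certainty (p = 0)
        as.numeric(abs(diff) < 1e-10 * scale)
      } else {
        2 * stats::pt(-abs(diff / se), fit$df.residual)
      }
      pmat[i, j] <- pmat[j, i] <- p
    }
  }
  if (adjust != "none") {
    up <- upper.tri(pmat)
    pmat[up] <- stats::p.adjust(pmat[up], method = adjust)
    pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  }
  letters <- compact_letters(pmat, alpha)
  list(means = data.frame(time_min = times, mean = unname(mu), n = nn,
                          letter = letters),
       p_matrix = pmat, alpha = alpha, model = fit)
}

#' Compact letter display
#'
#' Insert-and-absorb letter assignment: two levels share a letter if and
#' only if they are not significantly different (p >= alpha).
#'
#' @param pmat symmetric matrix of pairwise p values with level names on the
#'   dimnames.
#' @param alpha significance level.
#' @return Character vector of letter strings, one per level.
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  lv <- rownames(pmat)
  if (is.null(lv)) lv <- as.character(seq_len(nrow(pmat)))
  sets <- list(lv)
  for (i in seq_len(nrow(pmat) - 1)) {
    for (j in (i + 1):nrow(pmat)) {
      if (pmat[i, j] >= alpha) next
      a <- lv[i]; b <- lv[j]
      new_sets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      ## absorb: drop duplicates and any set strictly contained in another
      new_sets <- unique(lapply(new_sets, function(s) lv[lv %in% s]))
      keep <- rep(TRUE, length(new_sets))
      for (p in seq_along(new_sets)) {
        for (q in seq_along(new_sets)) {
          if (p != q && keep[q] && length(new_sets[[p]]) < length(new_sets[[q]]) &&
              all(new_sets[[p]] %in% new_sets[[q]])) {
            keep[p] <- FALSE
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  ## order sets by their earliest member for stable letter naming
  first <- vapply(sets, function(s) min(match(s, lv)), numeric(1))
  sets <- sets[order(first)]
  vapply(lv, function(l) {
    paste0(letters[which(vapply(sets, function(s) l %in% s, logical(1)))],
           collapse = "")
  }, character(1))
}

#' Pooled correlations between subpopulation proportions and endpoints
#'
#' Pearson correlation of every (subpopulation proportion, marker endpoint)
#' pair over all (incubation time, replicate) points pooled within one
#' sample type and medium. Two-sided p values come from the t transform
#' t = r * sqrt((n - 2) / (1 - r^2)); cells are flagged significant at
#' `alpha` (default 0.01).
#'
#' @param tc long-format time-course data.frame.
#' @param sample_type,medium condition selectors (default medium "CAP").
#' @param sp_endpoints names of the proportion endpoints.
#' @param marker_endpoints names of the marker endpoints.
#' @param alpha significance level (default 0.01).
#' @return Data.frame (sample_type, SP, endpoint, r, p, significant, n);
#'   `r` is NA when either series has zero variance.
#' @export
correlation_table <- function(tc, sample_type, medium = "CAP",
                              sp_endpoints = paste0("sp", 1:4, "_prop"),
                              marker_endpoints = c("mito_activity", "py_head",
                                                   "py_midpiece", "py_principal",
                                                   "py_tail"),
                              alpha = 0.01) {
  sub <- tc[tc$sample_type == sample_type & tc$medium == medium, , drop = FALSE]
  wide <- lapply(c(sp_endpoints, marker_endpoints), function(e) {
    v <- sub[sub$endpoint == e, ]
    stats::setNames(v$value, as.character(interaction(v$time_min, v$replicate_id,
                                                      drop = TRUE)))
  })
  names(wide) <- c(sp_endpoints, marker_endpoints)

  out <- do.call(rbind, lapply(sp_endpoints, function(sp) {
    do.call(rbind, lapply(marker_endpoints, function(mk) {
      common <- intersect(names(wide[[sp]]), names(wide[[mk]]))
      xs <- wide[[sp]][common]
      ys <- wide[[mk]][common]
      ok <- is.finite(xs) & is.finite(ys)
      xs <- xs[ok]; ys <- ys[ok]
      n <- length(xs)
      if (n < 4L) stop("fewer than 4 paired points for (", sp, ", ", mk, ")")
      if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
        return(data.frame(sample_type = sample_type, SP = sp, endpoint = mk,
                          r = NA_real_, p = NA_real_, significant = NA,
                          n = n, row.names = NULL))
      }
      r <- stats::cor(xs, ys)
      p <- if (abs(r) >= 1) 0 else
        2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
      data.frame(sample_type = sample_type, SP = sp, endpoint = mk,
                 r = r, p = p, significant = p < alpha, n = n,
                 row.names = NULL)
    }))
  }))
  out
}
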