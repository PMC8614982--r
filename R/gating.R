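## Imaging-flow-cytometry event gating and classification.
##
## Events arrive as per-event feature tables (mask-derived morphometrics plus
## channel intensities); pixel-level mask computation is upstream and out of
## scope. Canonical columns:
##   event_id, area (um^2), aspect_ratio, gradient_rms,
##   ch2_intensity (YO-PRO-1 or FITC), ch4_intensity (PI),
##   ch11_intensity (MitoTracker Deep Red),
##   head_aspect_ratio, head_length_um, pp_aspect_ratio, pp_length_um,
##   tail_aspect_ratio, tail_length_um, mp_aspect_ratio, mp_length_um,
##   py_head, py_midpiece, py_principal, py_tail (mean region fluorescence).

#' Gate sperm-compatible events
#'
#' Keeps events whose morphology is compatible with a single spermatozoon:
#' aspect ratio <= 0.40 and area between 50 and 400 um^2, all bounds
#' inclusive.
#'
#' @param events data.frame of cytometry events with `aspect_ratio` and
#'   `area` columns.
#' @param ar_max aspect-ratio ceiling (default 0.40).
#' @param area_min,area_max area window in um^2 (default 50-400).
#' @return List with `events` (the kept rows) and `report` (stage counts and
#'   a low-count flag).
#' @export
gate_sperm_events <- function(events, ar_max = 0.40, area_min = 50,
                              area_max = 400) {
  keep <- events$aspect_ratio <= ar_max &
    events$area >= area_min & events$area <= area_max
  kept <- events[keep, , drop = FALSE]
  report <- list(stages = c(input = nrow(events), sperm_gate = nrow(kept)),
                 low_count = nrow(kept) < 100)
  list(events = kept, report = report)
}

#' Stain positivity thresholds
#'
#' The quadrant analyses need a positivity cutoff per channel, which imaging
#' cytometry reports do not print. The default estimate splits each channel's
#' bimodal log-intensity distribution in two by 1-D 2-means and takes the
#' midpoint between the two centers (back-transformed). Cutoffs can always be
#' supplied explicitly instead.
#'
#' @param events gated events.
#' @param channels named character vector mapping threshold names to
#'   intensity columns.
#' @return Named list of positive cutoffs (a.u.), class `stain_thresholds`.
#' @export
estimate_stain_thresholds <- function(events,
                                      channels = c(yo_pro_pos = "ch2_intensity",
                                                   pi_pos = "ch4_intensity",
                                                   mito_pos = "ch11_intensity")) {
  out <- lapply(channels, function(col) {
    v <- log10(events[[col]] + 1)
    init <- stats::quantile(v, c(0.1, 0.9), names = FALSE)
    if (diff(init) < 1e-6) return(10^(mean(v)) - 1)  # degenerate: unimodal
    km <- stats::kmeans(v, centers = matrix(init, 2, 1), iter.max = 100,
                        algorithm = "Lloyd")
    10^mean(range(km$centers)) - 1
  })
  structure(as.list(out), class = "stain_thresholds")
}

#' Stain thresholds from explicit cutoffs
#' @param yo_pro_pos,pi_pos,mito_pos positive cutoffs (a.u., > 0).
#' @return A `stain_thresholds` list.
#' @export
stain_thresholds <- function(yo_pro_pos, pi_pos, mito_pos) {
  stopifnot(yo_pro_pos > 0, pi_pos > 0, mito_pos > 0)
  structure(list(yo_pro_pos = yo_pro_pos, pi_pos = pi_pos,
                 mito_pos = mito_pos), class = "stain_thresholds")
}

#' Quadrant classification for mitochondrial activity
#'
#' MitoTracker (ch11) against YO-PRO-1 (ch2): viable cells are YO-PRO-1
#' negative, active mitochondria are MitoTracker positive. Positivity means
#' intensity strictly above the cutoff.
#'
#' @param events gated events.
#' @param thresholds a `stain_thresholds` list.
#' @return List with `labels` (factor per event), `proportions` and `counts`
#'   over the four classes viable_active, viable_inactive, apoptotic_active,
#'   apoptotic_inactive.
#' @export
classify_mito <- function(events, thresholds) {
  if (nrow(events) == 0L) stop("no events: proportions undefined")
  mito_pos <- events$ch11_intensity > thresholds$mito_pos
  yopro_pos <- events$ch2_intensity > thresholds$yo_pro_pos
  lv <- c("viable_active", "viable_inactive",
          "apoptotic_active", "apoptotic_inactive")
  lab <- ifelse(!yopro_pos,
                ifelse(mito_pos, "viable_active", "viable_inactive"),
                ifelse(mito_pos, "apoptotic_active", "apoptotic_inactive"))
  labels <- factor(lab, levels = lv)
  counts <- table(labels)
  list(labels = labels,
       proportions = as.numeric(counts) / nrow(events),
       counts = counts)
}

#' Three-class viability classification
#'
#' YO-PRO-1 (ch2) against propidium iodide (ch4). Any PI-positive event is
#' classed dead (membrane-compromised) regardless of YO-PRO-1, so the three
#' classes partition all events; among PI-negative events, YO-PRO-1 positive
#' means apoptotic and negative viable.
#'
#' @inheritParams classify_mito
#' @return List with `labels`, `proportions`, `counts` over viable,
#'   apoptotic, dead.
#' @export
classify_viability <- function(events, thresholds) {
  if (nrow(events) == 0L) stop("no events: proportions undefined")
  pi_pos <- events$ch4_intensity > thresholds$pi_pos
  yopro_pos <- events$ch2_intensity > thresholds$yo_pro_pos
  lv <- c("viable", "apoptotic", "dead")
  lab <- ifelse(pi_pos, "dead", ifelse(yopro_pos, "apoptotic", "viable"))
  labels <- factor(lab, levels = lv)
  counts <- table(labels)
  list(labels = labels,
       proportions = as.numeric(counts) / nrow(events),
       counts = counts)
}

## Shared gate chain for the regional pY quantification. Returns the per-region
## mean fluorescence plus stage counts.
py_region_means <- function(events, pi_pos,
                            focus_range = c(65, 78),
                            area_range = c(25, 300), ar_max = 0.4,
                            head_ar_min = 0.4, head_len_max = 20,
                            pp_ar_max = 0.6, pp_len_max = 30,
                            tail_ar_max = 0.58, tail_len_max = 45,
                            mp_ar_max = 0.8, mp_len_max = 15) {
  live <- events[events$ch4_intensity <= pi_pos, , drop = FALSE]
  focused <- live[live$gradient_rms >= focus_range[1] &
                    live$gradient_rms <= focus_range[2], , drop = FALSE]
  single <- focused[focused$area >= area_range[1] &
                      focused$area <= area_range[2] &
                      focused$aspect_ratio < ar_max, , drop = FALSE]
  head <- single[single$head_aspect_ratio > head_ar_min &
                   single$head_length_um < head_len_max, , drop = FALSE]
  pp <- head[head$pp_aspect_ratio < pp_ar_max &
               head$pp_length_um < pp_len_max, , drop = FALSE]
  tail <- head[head$tail_aspect_ratio < tail_ar_max &
                 head$tail_length_um < tail_len_max, , drop = FALSE]
  mp <- pp[pp$mp_aspect_ratio < mp_ar_max &
             pp$mp_length_um < mp_len_max, , drop = FALSE]

  region_sets <- list(head = list(head, "py_head"),
                      midpiece = list(mp, "py_midpiece"),
                      principal_piece = list(pp, "py_principal"),
                      tail = list(tail, "py_tail"))
  means <- vapply(region_sets, function(rs) {
    if (nrow(rs[[1]]) == 0L) NA_real_ else mean(rs[[1]][[rs[[2]]]])
  }, numeric(1))
  stages <- c(input = nrow(events), live = nrow(live), focused = nrow(focused),
              single = nrow(single), true_head = nrow(head),
              true_principal_piece = nrow(pp), true_tail = nrow(tail),
              true_midpiece = nrow(mp))
  list(means = means, stages = stages)
}

#' Regional tyrosine-phosphorylation quantification with baseline
#' normalization
#'
#' Applies the full gate chain to a sample and to the baseline
#' (non-capacitating, 0 min, negative-control) events: exclude PI-positive
#' (dead) events, keep in-focus events (gradient RMS 65-78), keep single
#' sperm (area 25-300 um^2, aspect ratio < 0.4), then require correct mask
#' segmentation: true head (head aspect ratio > 0.4, head length < 20 um);
#' from the true-head set, true principal piece (aspect ratio < 0.6, length
#' < 30 um) and true tail (aspect ratio < 0.58, length < 45 um; the tail mask
#' covers midpiece plus principal piece); from true head AND true principal
#' piece, true midpiece (aspect ratio < 0.8, length < 15 um). Each region's
#' mean fluorescence over its surviving set is divided by the same region's
#' mean in the baseline.
#'
#' @param events sample event table.
#' @param baseline_events baseline event table (same schema).
#' @param thresholds a `stain_thresholds` list (only `pi_pos` is used).
#' @return List with `normalized` (named vector over head, midpiece,
#'   principal_piece, tail), `sample_means`, `baseline_means`, `report` and
#'   `baseline_report` (gate-stage counts).
#' @export
py_region_pipeline <- function(events, baseline_events, thresholds) {
  smp <- py_region_means(events, thresholds$pi_pos)
  base <- py_region_means(baseline_events, thresholds$pi_pos)
  if (any(!is.na(base$means) & base$means == 0)) {
    stop("baseline mean fluorescence is zero; normalization undefined")
  }
  if (any(is.na(smp$means))) {
    warning("no events survived the gate chain for region(s): ",
            paste(names(smp$means)[is.na(smp$means)], collapse = ", "))
  }
  list(normalized = smp$means / base$means,
       sample_means = smp$means,
       baseline_means = base$means,
       report = list(stages = smp$stages),
       baseline_report = list(stages = base$stages))
}
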