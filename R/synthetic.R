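## Synthetic-data generator with known ground truth for every input the
## pipeline consumes: kinematic mixtures, condition-dependent mixture
## weights, linked time-courses, and cytometry event tables.

#' Canonical kinematic profiles of the four motile ram sperm subpopulations
#'
#' Component mean matrix (4 subpopulations x 8 descriptors) used as the
#' generator default: SP1 slow-progressive, SP2 medium-progressive, SP3
#' fast-progressive, SP4 fastest/least linear with the highest lateral head
#' displacement (hyperactivated-like phenotype).
#'
#' @return 4 x 8 numeric matrix, rows SP1..SP4, columns [KINEMATIC_VARS].
#' @export
ram_subpopulation_means <- function() {
  m <- rbind(
    SP1 = c(26.38, 15.35, 21.32, 56.45, 75.44, 72.78, 1.23, 2.56),
    SP2 = c(75.78, 46.45, 66.49, 44.04, 59.79, 74.31, 2.02, 5.73),
    SP3 = c(162.12, 87.91, 151.93, 52.75, 58.55, 87.00, 2.91, 7.26),
    SP4 = c(183.64, 54.22, 163.15, 29.49, 35.43, 90.18, 5.42, 7.83))
  colnames(m) <- KINEMATIC_VARS
  m
}

#' Default mixture-weight trajectories over the incubation design
#'
#' Encodes the qualitative subpopulation dynamics of capacitating (CAP) and
#' non-capacitating (NC) incubation: in fresh sperm under CAP, SP1 declines
#' steadily while SP4 rises late (120-240 min, maximal at 240 min); in
#' frozen-thawed sperm under CAP, SP4 surges early (maximal at 15 min) then
#' declines while SP1 dips to 15 min and then recovers; under NC, SP1
#' dominates and SP4 stays scarce. The exact numbers are a package
#' convention (they are configuration data, not estimates).
#'
#' @return Data.frame with columns sample_type, medium, time_min,
#'   SP1..SP4; each weight row sums to 1.
#' @export
default_weight_trajectories <- function() {
  tr <- function(sample_type, medium, times, sp1, sp3, sp4) {
    data.frame(sample_type = sample_type, medium = medium, time_min = times,
               SP1 = sp1, SP2 = 1 - sp1 - sp3 - sp4, SP3 = sp3, SP4 = sp4)
  }
  rbind(
    tr("fresh", "CAP", c(1, 5, 15, 30, 60, 120, 180, 240),
       sp1 = c(0.45, 0.43, 0.38, 0.35, 0.30, 0.26, 0.22, 0.16),
       sp3 = c(0.28, 0.32, 0.34, 0.36, 0.38, 0.36, 0.32, 0.28),
       sp4 = c(0.05, 0.06, 0.07, 0.08, 0.10, 0.16, 0.24, 0.34)),
    tr("frozen_thawed", "CAP", c(1, 5, 15, 30, 60, 120, 180, 240),
       sp1 = c(0.38, 0.30, 0.14, 0.18, 0.26, 0.40, 0.50, 0.58),
       sp3 = c(0.25, 0.25, 0.25, 0.25, 0.25, 0.18, 0.15, 0.13),
       sp4 = c(0.15, 0.27, 0.42, 0.35, 0.25, 0.15, 0.09, 0.05)),
    tr("fresh", "NC", c(0, 15, 240),
       sp1 = c(0.55, 0.50, 0.42),
       sp3 = c(0.15, 0.17, 0.22),
       sp4 = c(0.05, 0.06, 0.06)),
    tr("frozen_thawed", "NC", c(0, 15, 240),
       sp1 = c(0.45, 0.48, 0.60),
       sp3 = c(0.25, 0.24, 0.15),
       sp4 = c(0.08, 0.06, 0.05)))
}

#' Default correlation targets linking subpopulations to capacitation markers
#'
#' Target pooled Pearson correlations between each subpopulation's
#' proportion and each capacitation endpoint under CAP conditions, per
#' sample type. Each endpoint is generated with a latent linear link to the
#' subpopulation carrying the largest absolute target in its row; the other
#' subpopulations' correlations then emerge through the weight-trajectory
#' geometry.
#'
#' @return Long data.frame (sample_type, endpoint, SP, rho).
#' @export
default_correlation_targets <- function() {
  mk <- function(sample_type, endpoint, rhos) {
    data.frame(sample_type = sample_type, endpoint = endpoint,
               SP = paste0("SP", 1:4), rho = rhos)
  }
  rbind(
    mk("fresh", "mito_activity", c(-0.18, -0.60, 0.83, 0.79)),
    mk("fresh", "py_head",       c(-0.84, -0.90, 0.29, 0.88)),
    mk("fresh", "py_midpiece",   c(-0.93, -0.91, 0.21, 0.91)),
    mk("fresh", "py_principal",  c(-0.97, -0.92, 0.21, 0.93)),
    mk("fresh", "py_tail",       c(-0.96, -0.95, 0.26, 0.96)),
    mk("frozen_thawed", "mito_activity", c(-0.99, -0.24, 0.63, 0.91)),
    mk("frozen_thawed", "py_head",       c(-0.93, -0.12, 0.59, 0.79)),
    mk("frozen_thawed", "py_midpiece",   c(-0.84, -0.56, 0.40, 0.90)),
    mk("frozen_thawed", "py_principal",  c(-0.69, -0.38, 0.64, 0.69)),
    mk("frozen_thawed", "py_tail",       c(-0.81, -0.60, 0.51, 0.86)))
}

#' Default cytometry event composition and stain-class fractions
#'
#' @return List with per-event-table composition fractions (`debris`,
#'   `out_of_focus`, `doublet`; remainder are single in-gate sperm), the
#'   fraction of sperm with failed mask segmentation (`bad_segmentation`),
#'   and stain-class fractions for the mitochondrial and viability panels.
#' @export
default_cytometry_fractions <- function() {
  list(debris = 0.20, out_of_focus = 0.05, doublet = 0.05,
       bad_segmentation = 0.10,
       mito_classes = c(viable_active = 0.60, viable_inactive = 0.00,
                        apoptotic_active = 0.15, apoptotic_inactive = 0.25),
       viability_classes = c(viable = 0.50, apoptotic = 0.20, dead = 0.30))
}

#' Regional pY intensity scale factors over the incubation design
#'
#' Multiplicative factors (relative to the 0 min NC baseline) applied to the
#' generated regional fluorescence: flagellar regions (midpiece, principal
#' piece, tail) rise strongly under CAP - early (peak 15-30 min) in
#' frozen-thawed sperm, late (120-240 min) in fresh sperm - while the head
#' barely changes and NC stays flat. Values are a package convention.
#'
#' @return Data.frame (sample_type, medium, time_min, head, midpiece,
#'   principal, tail).
#' @export
default_py_scales <- function() {
  row <- function(sample_type, medium, time_min, head, mid, pp, tl) {
    data.frame(sample_type = sample_type, medium = medium, time_min = time_min,
               head = head, midpiece = mid, principal = pp, tail = tl)
  }
  cap_t <- c(1, 5, 15, 30, 60, 120, 180, 240)
  rbind(
    do.call(rbind, Map(row, "fresh", "CAP", cap_t,
                       head = c(1.00, 1.00, 1.02, 1.05, 1.08, 1.12, 1.20, 1.28),
                       mid = c(1.00, 1.05, 1.15, 1.25, 1.45, 1.75, 2.10, 2.20),
                       pp  = c(1.00, 1.05, 1.10, 1.20, 1.40, 1.80, 1.95, 2.00),
                       tl  = c(1.00, 1.05, 1.12, 1.22, 1.42, 1.78, 2.05, 2.10))),
    do.call(rbind, Map(row, "frozen_thawed", "CAP", cap_t,
                       head = c(1.05, 1.08, 1.10, 1.08, 1.02, 0.95, 0.90, 0.85),
                       mid = c(1.20, 1.70, 2.20, 2.10, 1.70, 1.40, 1.20, 1.10),
                       pp  = c(1.15, 1.55, 1.90, 1.75, 1.50, 1.30, 1.15, 1.05),
                       tl  = c(1.18, 1.65, 2.10, 2.00, 1.62, 1.36, 1.18, 1.08))),
    do.call(rbind, Map(row, "fresh", "NC", c(0, 15, 240),
                       head = 1, mid = c(1, 1.02, 1.05),
                       pp = c(1, 1.01, 1.04), tl = c(1, 1.02, 1.05))),
    do.call(rbind, Map(row, "frozen_thawed", "NC", c(0, 15, 240),
                       head = 1, mid = c(1, 1.02, 1.03),
                       pp = c(1, 1.01, 1.02), tl = c(1, 1.02, 1.03))))
}

#' Assemble a synthetic scenario
#'
#' Bundles every generator parameter: the 4 x 8 component mean matrix, the
#' per-variable coefficient of variation, the mixture-weight trajectories,
#' per-condition sample size, correlation targets, cytometry composition,
#' the number of spermatozoa counted per CASA evaluation (multinomial
#' denominator for observed proportions) and the seed.
#'
#' Component means are checked against the ratio identities
#' LIN = 100*VSL/VCL and WOB = 100*VAP/VCL; deviations beyond `ratio_check`
#' raise a warning, not an error, because the generator samples VCL, LIN,
#' ALH, BCF and WOB and derives VSL, VAP and STR, so generated records are
#' exactly self-consistent regardless of the mean matrix (published
#' subpopulation tables are themselves not always internally consistent).
#'
#' @param component_means 4 x 8 matrix (rows = subpopulations, columns =
#'   [KINEMATIC_VARS]).
#' @param component_cv within-component coefficient of variation (sd =
#'   cv * mean), default 0.12.
#' @param weights weight-trajectory data.frame as from
#'   [default_weight_trajectories()].
#' @param n_per_condition spermatozoa generated per (sample_type, medium,
#'   time) condition, default 2000.
#' @param correlation_targets as from [default_correlation_targets()].
#' @param cytometry_fractions as from [default_cytometry_fractions()].
#' @param py_scales as from [default_py_scales()].
#' @param n_counted spermatozoa counted per time-course evaluation
#'   (default 200).
#' @param seed integer default seed.
#' @param ratio_check relative tolerance of the mean-matrix consistency
#'   warning (default 0.10).
#' @return List of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(component_means = ram_subpopulation_means(),
                               component_cv = 0.12,
                               weights = default_weight_trajectories(),
                               n_per_condition = 2000,
                               correlation_targets = default_correlation_targets(),
                               cytometry_fractions = default_cytometry_fractions(),
                               py_scales = default_py_scales(),
                               n_counted = 200,
                               seed = 1,
                               ratio_check = 0.10) {
  stopifnot(is.matrix(component_means), ncol(component_means) == 8,
            component_cv >= 0, n_per_condition >= 1, n_counted >= 1)
  colnames(component_means) <- KINEMATIC_VARS
  if (is.null(rownames(component_means))) {
    rownames(component_means) <- paste0("SP", seq_len(nrow(component_means)))
  }

  wsum <- rowSums(weights[, rownames(component_means)])
  if (any(abs(wsum - 1) > 1e-9)) stop("weight vectors must sum to 1")
  if (any(weights[, rownames(component_means)] < 0)) stop("negative mixture weight")
  if (any(abs(correlation_targets$rho) > 1)) stop("|rho| must be <= 1")

  lin_imp <- 100 * component_means[, "VSL"] / component_means[, "VCL"]
  wob_imp <- 100 * component_means[, "VAP"] / component_means[, "VCL"]
  lin_dev <- abs(component_means[, "LIN"] - lin_imp) / lin_imp
  wob_dev <- abs(component_means[, "WOB"] - wob_imp) / wob_imp
  if (any(c(lin_dev, wob_dev) > ratio_check)) {
    warning("component means deviate from the ratio identities by more than ",
            round(100 * ratio_check), "% for: ",
            paste(unique(rownames(component_means)[lin_dev > ratio_check |
                                                     wob_dev > ratio_check]),
                  collapse = ", "),
            " (generated records are still exactly consistent)")
  }

  structure(list(component_means = component_means,
                 component_cv = component_cv,
                 weights = weights,
                 n_per_condition = as.integer(n_per_condition),
                 correlation_targets = correlation_targets,
                 cytometry_fractions = cytometry_fractions,
                 py_scales = py_scales,
                 n_counted = as.integer(n_counted),
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

## Vectorized truncated-normal draws by rejection; sd may be 0 (degenerate).
rtrunc_norm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (length(mean) == 1L) mean <- rep(mean, n)
  if (length(sd) == 1L) sd <- rep(sd, n)
  out <- stats::rnorm(n, mean, sd)
  for (iter in 1:1000) {
    bad <- out < lower | out > upper
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  }
  out[out < lower] <- lower
  out[out > upper] <- upper
  out
}

#' Generate a synthetic kinematic dataset with ground-truth labels
#'
#' For every condition in the scenario's weight table (restricted to
#' `sample_types`), draws each spermatozoon's subpopulation from the mixture
#' weights, then draws VCL, LIN, ALH, BCF and WOB from independent truncated
#' normals (mean = component mean, sd = cv * mean; velocities truncated at 0,
#' ratios within (0, 100), and LIN < WOB enforced by redrawing the pair so
#' straightness stays below 100%). VSL = LIN*VCL/100, VAP = WOB*VCL/100 and
#' STR = 100*VSL/VAP are derived, so the ratio identities hold exactly on
#' every generated record.
#'
#' @param scn a [synthetic_scenario].
#' @param sample_types which sample types to generate (default both).
#' @param seed integer seed (default the scenario's).
#' @param n_replicates replicate labels cycled over records (default 3).
#' @return List with `dataset` (a [kinematic_dataset]) and `labels`
#'   (factor of true components, same order as the records).
#' @export
generate_kinematics <- function(scn, sample_types = c("fresh", "frozen_thawed"),
                                seed = scn$seed, n_replicates = 3) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  set.seed(seed)
  mu <- scn$component_means
  cv <- scn$component_cv
  sps <- rownames(mu)
  wtab <- scn$weights[scn$weights$sample_type %in% sample_types, , drop = FALSE]

  blocks <- vector("list", nrow(wtab))
  labels <- vector("list", nrow(wtab))
  for (i in seq_len(nrow(wtab))) {
    n <- scn$n_per_condition
    w <- as.numeric(wtab[i, sps])
    comp <- sample(seq_along(sps), n, replace = TRUE, prob = w)

    vcl <- rtrunc_norm(n, mu[comp, "VCL"], cv * mu[comp, "VCL"], lower = 0)
    alh <- rtrunc_norm(n, mu[comp, "ALH"], cv * mu[comp, "ALH"], lower = 0)
    bcf <- rtrunc_norm(n, mu[comp, "BCF"], cv * mu[comp, "BCF"], lower = 0)
    lin <- rtrunc_norm(n, mu[comp, "LIN"], cv * mu[comp, "LIN"], 0, 100)
    wob <- rtrunc_norm(n, mu[comp, "WOB"], cv * mu[comp, "WOB"], 0, 100)
    ## keep straightness below 100%: redraw (LIN, WOB) pairs with LIN >= WOB
    for (iter in 1:1000) {
      bad <- lin >= wob
      if (!any(bad)) break
      nb <- sum(bad)
      lin[bad] <- rtrunc_norm(nb, mu[comp[bad], "LIN"],
                              cv * mu[comp[bad], "LIN"], 0, 100)
      wob[bad] <- rtrunc_norm(nb, mu[comp[bad], "WOB"],
                              cv * mu[comp[bad], "WOB"], 0, 100)
    }
    if (any(lin >= wob)) lin[lin >= wob] <- wob[lin >= wob] * 0.999

    vsl <- lin * vcl / 100
    vap <- wob * vcl / 100
    str_ <- 100 * vsl / pmax(vap, .Machine$double.eps)
    str_[vap == 0] <- 0

    blocks[[i]] <- data.frame(
      VCL = vcl, VSL = vsl, VAP = vap, LIN = lin, STR = str_, WOB = wob,
      ALH = alh, BCF = bcf,
      sample_type = wtab$sample_type[i], medium = wtab$medium[i],
      time_min = wtab$time_min[i],
      replicate_id = paste0("R", rep_len(seq_len(n_replicates), n)),
      sperm_id = sprintf("%s_%s_t%03d_%05d", wtab$sample_type[i],
                         wtab$medium[i], wtab$time_min[i], seq_len(n)))
    labels[[i]] <- sps[comp]
  }
  records <- do.call(rbind, blocks)
  ds <- kinematic_dataset(records, provenance = "synthetic_scenario",
                          ratio_tol = 0.02)
  list(dataset = ds,
       labels = factor(do.call(c, labels), levels = sps))
}

#' Noise standard deviation achieving a target correlation
#'
#' For an endpoint built as y = a + b*x + e with driver sd `sd_x`, the
#' Pearson correlation between y and x equals `rho` exactly when
#' sd(e) = |b| * sd_x * sqrt(1/rho^2 - 1).
#'
#' @param rho target correlation, |rho| in (0, 1].
#' @param sd_x driver standard deviation (> 0).
#' @param slope linear link slope b.
#' @return The required noise sd (0 when |rho| = 1).
#' @export
calibrate_noise <- function(rho, sd_x, slope) {
  stopifnot(abs(rho) > 0, abs(rho) <= 1, sd_x > 0)
  abs(slope) * sd_x * sqrt(1 / rho^2 - 1)
}

#' Generate a linked time-course table
#'
#' For every condition and replicate, emits observed subpopulation
#' proportions (multinomial counts of `n_counted` spermatozoa over the
#' latent mixture weights, normalized) and capacitation endpoints
#' (mitochondrial activity and regional pY). Under CAP, each endpoint is
#' linearly linked to the latent weight of the subpopulation carrying the
#' largest |rho| in its correlation-target row, with noise calibrated by
#' [calibrate_noise()] so the pooled correlation with that driver matches
#' the target; the slope sign follows the target sign. Under NC, endpoints
#' are unlinked noise around their baseline level, matching the absence of
#' significant NC correlations.
#'
#' @param scn a [synthetic_scenario].
#' @param sample_types sample types to generate (default both).
#' @param medium "CAP" (default) or "NC".
#' @param n_replicates replicates per time (default 3).
#' @param seed integer seed.
#' @return Long time-course data.frame (sample_type, medium, time_min,
#'   replicate_id, endpoint, value) with the link parameters attached as
#'   attribute `"truth"`.
#' @export
generate_linked_timecourse <- function(scn,
                                       sample_types = c("fresh", "frozen_thawed"),
                                       medium = "CAP", n_replicates = 3,
                                       seed = scn$seed) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  set.seed(seed)
  sps <- rownames(scn$component_means)
  ep_level <- c(mito_activity = 0.45, py_head = 1.6, py_midpiece = 1.6,
                py_principal = 1.6, py_tail = 1.6)
  ep_sd <- c(mito_activity = 0.12, py_head = 0.45, py_midpiece = 0.45,
             py_principal = 0.45, py_tail = 0.45)

  rows <- list()
  truth <- list()
  for (st in sample_types) {
    wt <- scn$weights[scn$weights$sample_type == st &
                        scn$weights$medium == medium, , drop = FALSE]
    wt <- wt[order(wt$time_min), ]
    times <- wt$time_min
    wlat <- as.matrix(wt[, sps])          # times x 4 latent weights

    ## design: every time replicated n_replicates times
    design_t <- rep(seq_along(times), each = n_replicates)
    rep_id <- paste0("R", rep_len(seq_len(n_replicates), length(design_t)))

    ## observed proportions: multinomial counting noise
    props <- t(vapply(design_t, function(ti) {
      as.numeric(stats::rmultinom(1, scn$n_counted, wlat[ti, ])) / scn$n_counted
    }, numeric(length(sps))))
    colnames(props) <- sps

    for (j in seq_along(sps)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_type = st, medium = medium, time_min = times[design_t],
        replicate_id = rep_id,
        endpoint = paste0(tolower(sps[j]), "_prop"), value = props[, j])
    }

    tg <- scn$correlation_targets[scn$correlation_targets$sample_type == st, ]
    for (ep in unique(tg$endpoint)) {
      trow <- tg[tg$endpoint == ep, ]
      if (medium == "CAP") {
        d <- which.max(abs(trow$rho))
        rho <- trow$rho[d]
        x <- wlat[design_t, trow$SP[d]]
        sd_x <- stats::sd(x)
        slope <- sign(rho) * ep_sd[[ep]] / sd_x
        a <- ep_level[[ep]] - slope * mean(x)
        sd_e <- calibrate_noise(rho, sd_x, slope)
        value <- a + slope * x + stats::rnorm(length(x), 0, sd_e)
        truth[[length(truth) + 1L]] <- data.frame(
          sample_type = st, endpoint = ep, driver = trow$SP[d], rho = rho,
          intercept = a, slope = slope, noise_sd = sd_e)
      } else {
        value <- stats::rnorm(length(design_t), ep_level[[ep]], ep_sd[[ep]] / 2)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_type = st, medium = medium, time_min = times[design_t],
        replicate_id = rep_id, endpoint = ep, value = value)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- if (length(truth)) do.call(rbind, truth) else NULL
  out
}

## Log-normal intensity draws around a population mode.
rintensity <- function(n, mode, sdlog = 0.35) {
  stats::rlnorm(n, meanlog = log(mode), sdlog = sdlog)
}

#' Generate a cytometry event table with ground truth
#'
#' Emits `n_events` events: in-gate single sperm plus debris (off the
#' aspect-ratio/area gate), out-of-focus events (gradient RMS outside
#' 65-78) and doublets (area above the single-cell window), at the
#' scenario's composition fractions. Stain intensities are log-normal
#' around well-separated negative/positive modes per class; regional pY
#' fluorescence is scaled by the condition's factor relative to the 0 min
#' NC baseline. Ground truth (event class, stain class, segmentation
#' status) is carried in `true_*` columns.
#'
#' @param scn a [synthetic_scenario].
#' @param sample_type,medium,time_min condition generating the regional pY
#'   scale (must exist in `scn$py_scales`).
#' @param panel "mito", "viability" or "py": which stain panel's class
#'   fractions drive ch2/ch4/ch11 (the pY panel uses the viability dead
#'   fraction for PI and FITC in ch2).
#' @param n_events events to generate (default 10000).
#' @param seed integer seed.
#' @return Data.frame of events in the canonical schema plus truth columns.
#' @export
generate_cytometry_events <- function(scn, sample_type = "frozen_thawed",
                                      medium = "CAP", time_min = 15,
                                      panel = c("mito", "viability", "py"),
                                      n_events = 10000, seed = scn$seed) {
  stopifnot(inherits(scn, "synthetic_scenario"))
  panel <- match.arg(panel)
  set.seed(seed)
  fr <- scn$cytometry_fractions
  stopifnot(fr$debris + fr$out_of_focus + fr$doublet < 1)

  n_debris <- round(n_events * fr$debris)
  n_oof <- round(n_events * fr$out_of_focus)
  n_doub <- round(n_events * fr$doublet)
  n_sperm <- n_events - n_debris - n_oof - n_doub

  neg_mode <- 50
  pos_mode <- 1000

  mk_block <- function(n, class) {
    if (n == 0L) return(NULL)
    df <- data.frame(
      area = stats::runif(n, 55, 295),
      aspect_ratio = stats::runif(n, 0.05, 0.38),
      gradient_rms = stats::runif(n, 66, 77),
      true_event_class = class)
    if (class == "debris") {
      half <- seq_len(n) <= n / 2
      df$area[half] <- stats::runif(sum(half), 5, 45)
      df$aspect_ratio[!half] <- stats::runif(sum(!half), 0.45, 0.95)
    } else if (class == "doublet") {
      df$area <- stats::runif(n, 305, 395)
    } else if (class == "out_of_focus") {
      lowhalf <- seq_len(n) <= n / 2
      df$gradient_rms[lowhalf] <- stats::runif(sum(lowhalf), 40, 62)
      df$gradient_rms[!lowhalf] <- stats::runif(sum(!lowhalf), 80, 95)
    }
    df
  }
  ev <- rbind(mk_block(n_sperm, "sperm"), mk_block(n_debris, "debris"),
              mk_block(n_oof, "out_of_focus"), mk_block(n_doub, "doublet"))
  n_all <- nrow(ev)

  ## stain classes: carried by every cell-like event (sperm, out-of-focus,
  ## doublet) - the mito/viability panels gate only on aspect ratio and
  ## area, so their class fractions apply to everything that survives that
  ## gate; debris stays unstained (dim in every channel)
  class_frac <- switch(panel,
                       mito = fr$mito_classes,
                       viability = fr$viability_classes,
                       py = fr$viability_classes)
  if (abs(sum(class_frac) - 1) > 1e-9) stop("class fractions must sum to 1")
  is_cell <- ev$true_event_class != "debris"
  stain <- rep(NA_character_, n_all)
  stain[is_cell] <- sample(names(class_frac), sum(is_cell), replace = TRUE,
                           prob = class_frac)

  ch2 <- rintensity(n_all, neg_mode)
  ch4 <- rintensity(n_all, neg_mode)
  ch11 <- rintensity(n_all, neg_mode)
  if (panel == "mito") {
    ch2[stain %in% c("apoptotic_active", "apoptotic_inactive")] <-
      rintensity(sum(stain %in% c("apoptotic_active", "apoptotic_inactive"),
                     na.rm = TRUE), pos_mode)
    ch11[stain %in% c("viable_active", "apoptotic_active")] <-
      rintensity(sum(stain %in% c("viable_active", "apoptotic_active"),
                     na.rm = TRUE), pos_mode)
  } else {
    ch2[stain %in% "apoptotic"] <- rintensity(sum(stain %in% "apoptotic"),
                                              pos_mode)
    ch4[stain %in% "dead"] <- rintensity(sum(stain %in% "dead"), pos_mode)
  }

  ## mask morphometrics: well-segmented cells pass every mask gate; a
  ## bad_segmentation fraction fails at least one
  seg_ok <- is_cell & stats::runif(n_all) > fr$bad_segmentation
  nn <- n_all
  morph <- data.frame(
    head_aspect_ratio = stats::runif(nn, 0.45, 0.85),
    head_length_um = stats::runif(nn, 6, 12),
    pp_aspect_ratio = stats::runif(nn, 0.10, 0.55),
    pp_length_um = stats::runif(nn, 16, 28),
    tail_aspect_ratio = stats::runif(nn, 0.10, 0.55),
    tail_length_um = stats::runif(nn, 28, 43),
    mp_aspect_ratio = stats::runif(nn, 0.30, 0.75),
    mp_length_um = stats::runif(nn, 7, 13))
  bad <- which(!seg_ok)
  if (length(bad)) {
    which_gate <- sample(1:4, length(bad), replace = TRUE)
    morph$head_aspect_ratio[bad[which_gate == 1]] <- stats::runif(sum(which_gate == 1), 0.05, 0.38)
    morph$pp_length_um[bad[which_gate == 2]] <- stats::runif(sum(which_gate == 2), 31, 45)
    morph$tail_length_um[bad[which_gate == 3]] <- stats::runif(sum(which_gate == 3), 46, 60)
    morph$mp_length_um[bad[which_gate == 4]] <- stats::runif(sum(which_gate == 4), 16, 25)
  }

  ## regional pY fluorescence, scaled relative to the 0 min NC baseline
  ps <- scn$py_scales
  sc <- ps[ps$sample_type == sample_type & ps$medium == medium &
             ps$time_min == time_min, , drop = FALSE]
  if (nrow(sc) != 1L) stop("no pY scale for condition ", sample_type, "/",
                           medium, "/", time_min)
  base_mode <- c(head = 120, midpiece = 100, principal = 90, tail = 95)
  py <- data.frame(
    py_head = rintensity(nn, base_mode["head"] * sc$head, sdlog = 0.3),
    py_midpiece = rintensity(nn, base_mode["midpiece"] * sc$midpiece, sdlog = 0.3),
    py_principal = rintensity(nn, base_mode["principal"] * sc$principal, sdlog = 0.3),
    py_tail = rintensity(nn, base_mode["tail"] * sc$tail, sdlog = 0.3))

  out <- cbind(data.frame(event_id = sprintf("ev%06d", seq_len(nn))),
               ev[, c("area", "aspect_ratio", "gradient_rms")],
               data.frame(ch2_intensity = ch2, ch4_intensity = ch4,
                          ch11_intensity = ch11),
               morph, py,
               data.frame(true_event_class = ev$true_event_class,
                          true_stain_class = stain,
                          true_seg_ok = seg_ok))
  rownames(out) <- NULL
  ## shuffle so event order carries no class information
  out[sample.int(nn), ]
}
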