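thr <- stain_thresholds(yo_pro_pos = 224, pi_pos = 224, mito_pos = 224)

base_event <- function(n = 1, ...) {
  df <- data.frame(
    event_id = sprintf("e%03d", seq_len(n)),
    area = 150, aspect_ratio = 0.2, gradient_rms = 70,
    ch2_intensity = 50, ch4_intensity = 50, ch11_intensity = 50,
    head_aspect_ratio = 0.6, head_length_um = 9,
    pp_aspect_ratio = 0.3, pp_length_um = 22,
    tail_aspect_ratio = 0.3, tail_length_um = 35,
    mp_aspect_ratio = 0.5, mp_length_um = 10,
    py_head = 100, py_midpiece = 100, py_principal = 100, py_tail = 100)
  mods <- list(...)
  for (nm in names(mods)) df[[nm]] <- mods[[nm]]
  df
}

test_that("the sperm gate honors its printed closed bounds exactly", {
  ev <- rbind(base_event(1, aspect_ratio = 0.40, area = 50),   # boundary in
              base_event(1, aspect_ratio = 0.40, area = 400),  # boundary in
              base_event(1, aspect_ratio = 0.41, area = 200),  # ar out
              base_event(1, aspect_ratio = 0.20, area = 49.9), # area out
              base_event(1, aspect_ratio = 0.20, area = 400.1))
  g <- gate_sperm_events(ev)
  expect_equal(nrow(g$events), 2)
  expect_equal(unname(g$report$stages), c(5, 2))
})

test_that("quadrant classifications partition their input", {
  ev <- rbind(base_event(1),                                    # both negative
              base_event(1, ch11_intensity = 1000),             # mito+ only
              base_event(1, ch2_intensity = 1000),              # yopro+ only
              base_event(1, ch2_intensity = 1000, ch11_intensity = 1000))
  cm <- classify_mito(ev, thr)
  expect_equal(as.character(cm$labels),
               c("viable_inactive", "viable_active",
                 "apoptotic_inactive", "apoptotic_active"))
  expect_equal(sum(cm$proportions), 1)
  expect_equal(sum(cm$counts), nrow(ev))

  # PI-high events are dead regardless of YO-PRO-1
  ev2 <- rbind(base_event(1, ch4_intensity = 1000),
               base_event(1, ch4_intensity = 1000, ch2_intensity = 1000),
               base_event(1, ch2_intensity = 1000),
               base_event(1))
  cv <- classify_viability(ev2, thr)
  expect_equal(as.character(cv$labels), c("dead", "dead", "apoptotic", "viable"))
  expect_equal(sum(cv$proportions), 1)
  expect_error(classify_mito(ev[0, ], thr), "no events")
})

test_that("generated class fractions are recovered within three binomial SEs", {
  scn <- default_scn()
  for (panel in c("mito", "viability")) {
    ev <- generate_cytometry_events(scn, panel = panel, n_events = 10000,
                                    seed = 31)
    g <- gate_sperm_events(ev)
    expect_equal(nrow(g$events),
                 sum(ev$true_event_class != "debris"))
    th <- estimate_stain_thresholds(g$events)
    cls <- if (panel == "mito") classify_mito(g$events, th) else
      classify_viability(g$events, th)
    truth <- if (panel == "mito") scn$cytometry_fractions$mito_classes else
      scn$cytometry_fractions$viability_classes
    n <- nrow(g$events)
    for (i in seq_along(truth)) {
      se <- sqrt(max(truth[i] * (1 - truth[i]), 1e-6) / n)
      expect_lt(abs(cls$proportions[i] - truth[i]), 3 * se + 1e-9)
    }
    # classification partitions the gated input
    expect_equal(sum(cls$counts), n)
  }
})

test_that("every mask gate boundary is honored as printed (open bounds)", {
  ok <- base_event(1)
  variants <- list(
    list(col = "head_aspect_ratio", val = 0.4, kept = FALSE),  # needs > 0.4
    list(col = "head_length_um", val = 20, kept = FALSE),      # needs < 20
    list(col = "pp_aspect_ratio", val = 0.6, kept = FALSE),    # needs < 0.6
    list(col = "pp_length_um", val = 30, kept = FALSE),
    list(col = "tail_aspect_ratio", val = 0.58, kept = FALSE),
    list(col = "tail_length_um", val = 45, kept = FALSE),
    list(col = "mp_aspect_ratio", val = 0.8, kept = FALSE),
    list(col = "mp_length_um", val = 15, kept = FALSE))
  for (v in variants) {
    ev <- base_event(1)
    ev[[v$col]] <- v$val
    res <- suppressWarnings(py_region_pipeline(ev, ok, thr))
    region <- switch(v$col,
                     head_aspect_ratio = , head_length_um = "head",
                     pp_aspect_ratio = , pp_length_um = "principal_piece",
                     tail_aspect_ratio = , tail_length_um = "tail",
                     mp_aspect_ratio = , mp_length_um = "midpiece")
    expect_true(is.na(res$normalized[region]),
                label = paste(v$col, "boundary should exclude the event"))
  }
  # head failure cascades to every downstream mask
  ev <- base_event(1, head_length_um = 25)
  res <- suppressWarnings(py_region_pipeline(ev, ok, thr))
  expect_true(all(is.na(res$normalized)))
})

test_that("pY gate chain counts are non-increasing and self-normalization is exact", {
  scn <- default_scn()
  ev <- generate_cytometry_events(scn, sample_type = "frozen_thawed",
                                  medium = "CAP", time_min = 15,
                                  panel = "py", n_events = 5000, seed = 32)
  res <- py_region_pipeline(ev, ev, thr)
  expect_true(all(diff(res$report$stages[c("input", "live", "focused",
                                           "single", "true_head")]) <= 0))
  expect_lte(res$report$stages["true_midpiece"],
             res$report$stages["true_principal_piece"])
  expect_lte(res$report$stages["true_principal_piece"],
             res$report$stages["true_head"])
  expect_equal(unname(res$normalized),
               rep(1, 4))                 # exact self-normalization
})

test_that("a constructed six-event fixture quantifies the midpiece over survivors only", {
  ev <- rbind(
    base_event(1, py_midpiece = 200),                      # passes everything
    base_event(1, py_midpiece = 400),                      # passes everything
    base_event(1, py_midpiece = 999, mp_length_um = 18),   # fails midpiece mask
    base_event(1, py_midpiece = 999, head_length_um = 25), # fails head mask
    base_event(1, py_midpiece = 999, ch4_intensity = 5000),# dead, excluded first
    base_event(1, py_midpiece = 999, gradient_rms = 50))   # out of focus
  baseline <- base_event(2, py_midpiece = 100)
  res <- suppressWarnings(py_region_pipeline(ev, baseline, thr))
  expect_equal(unname(res$sample_means["midpiece"]), 300)
  expect_equal(unname(res$normalized["midpiece"]), 3)
})

test_that("normalized pY is invariant to a common intensity rescaling", {
  scn <- default_scn()
  ev <- generate_cytometry_events(scn, panel = "py", n_events = 3000, seed = 33)
  base <- generate_cytometry_events(scn, sample_type = "fresh", medium = "NC",
                                    time_min = 0, panel = "py",
                                    n_events = 3000, seed = 34)
  r1 <- py_region_pipeline(ev, base, thr)
  sc <- function(df) {
    df[c("py_head", "py_midpiece", "py_principal", "py_tail")] <-
      df[c("py_head", "py_midpiece", "py_principal", "py_tail")] * 7.5
    df
  }
  r2 <- py_region_pipeline(sc(ev), sc(base), thr)
  expect_equal(r1$normalized, r2$normalized, tolerance = 1e-12)
})

test_that("capacitating frozen-thawed 15 min midpiece pY exceeds the NC baseline", {
  scn <- default_scn()
  ev <- generate_cytometry_events(scn, sample_type = "frozen_thawed",
                                  medium = "CAP", time_min = 15,
                                  panel = "py", n_events = 6000, seed = 35)
  base <- generate_cytometry_events(scn, sample_type = "fresh", medium = "NC",
                                    time_min = 0, panel = "py",
                                    n_events = 6000, seed = 36)
  res <- py_region_pipeline(ev, base, thr)
  expect_gt(res$normalized["midpiece"], 1)
  expect_gt(res$normalized["tail"], 1)
})
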