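test_that("standardization centers, scales, is idempotent and rejects constants", {
  x <- matrix(c(1, 2, 3, 10, 20, 30), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  std <- standardize_kinematics(x)
  # sample-sd convention: column (1,2,3) maps exactly to (-1, 0, 1)
  expect_equal(unname(std$scaled[, 1]), c(-1, 0, 1))
  expect_true(all(abs(colMeans(std$scaled)) < 1e-9))
  expect_true(all(abs(apply(std$scaled, 2, sd) - 1) < 1e-9))

  again <- standardize_kinematics(std$scaled)
  expect_equal(again$scaled, std$scaled, tolerance = 1e-12)

  xc <- cbind(x, cc = c(5, 5, 5))
  expect_error(standardize_kinematics(xc), "zero-variance column.*cc")
})

test_that("k-means recovers trivial structure and is seed-deterministic", {
  # k distinct repeated points: zero inertia, centroids equal the points
  pts <- matrix(c(0, 0, 10, 0, 0, 10), 3, byrow = TRUE)
  x <- pts[rep(1:3, each = 5), ]
  km <- kmeans_step1(x, 3, n_restarts = 5, seed = 1)
  expect_equal(km$tot_withinss, 0)
  expect_equal(dim(km$centers), c(3, 2))
  expect_setequal(apply(round(km$centers), 1, paste, collapse = ","),
                  apply(pts, 1, paste, collapse = ","))

  # two 1-D clouds at 0 and 100 split exactly
  set.seed(2)
  y <- matrix(c(rnorm(20, 0), rnorm(20, 100)), ncol = 1)
  km2 <- kmeans_step1(y, 2, n_restarts = 5, seed = 3)
  expect_equal(length(unique(km2$cluster[1:20])), 1)
  expect_equal(length(unique(km2$cluster[21:40])), 1)

  km3 <- kmeans_step1(y, 2, n_restarts = 5, seed = 3)
  expect_identical(km2$cluster, km3$cluster)
})

test_that("step-1 centroids lie inside their clusters' convex hull (coordinate-wise)", {
  scn <- default_scn(n_per_condition = 150)
  g <- generate_kinematics(scn, sample_types = "fresh", seed = 5)
  mat <- standardize_kinematics(
    as.matrix(g$dataset$records[, c("VCL", "LIN", "ALH", "BCF")]))$scaled
  km <- kmeans_step1(mat, 12, n_restarts = 5, seed = 5)
  for (cl in seq_len(12)) {
    members <- mat[km$cluster == cl, , drop = FALSE]
    expect_true(all(km$centers[cl, ] >= apply(members, 2, min) - 1e-9))
    expect_true(all(km$centers[cl, ] <= apply(members, 2, max) + 1e-9))
  }
})

test_that("silhouette scan selects the blob count and ties go to smallest k", {
  centers <- matrix(c(0, 0, 12, 0, 0, 12, 12, 12), 4, byrow = TRUE)
  x <- make_blobs(4, 40, centers, sd = 0.6, seed = 4)
  cfg <- clustering_config(k_range_step1 = 2:8, n_restarts = 5)
  expect_equal(select_k_step1(x, cfg, seed = 1)$k, 4)

  x2 <- make_blobs(2, 50, centers[1:2, ], sd = 0.6, seed = 5)
  cfg2 <- clustering_config(k_range_step1 = 2:6, n_restarts = 5)
  expect_equal(select_k_step1(x2, cfg2, seed = 1)$k, 2)
})

test_that("ward merge of two singleton centroids happens at their distance", {
  cents <- matrix(c(0, 0, 3, 4), 2, byrow = TRUE)
  hc <- hierarchical_merge(cents, "ward")
  expect_equal(hc$height, 5)
  # merge heights are non-decreasing on any input
  set.seed(6)
  hc2 <- hierarchical_merge(matrix(rnorm(40), ncol = 2), "ward")
  expect_true(all(diff(hc2$height) >= -1e-12))
  hc3 <- hierarchical_merge(matrix(rnorm(40), ncol = 2), "average")
  expect_true(all(diff(hc3$height) >= -1e-12))
})

test_that("final-k selection agrees with truth on separated blobs", {
  centers <- matrix(c(0, 0, 12, 0, 0, 12, 12, 12), 4, byrow = TRUE)
  x <- make_blobs(4, 50, centers, sd = 0.6, seed = 7)
  km <- kmeans_step1(x, 12, n_restarts = 5, seed = 7)
  dend <- hierarchical_merge(km$centers)
  cfg <- clustering_config(final_k_range = 2:8)
  fin <- select_final_k(dend, dist(x), cfg, step1_labels = km$cluster)
  expect_equal(fin$final_k, 4)
  expect_equal(fin$candidate_gamma, 4L)
  expect_equal(fin$candidate_lmethod, 4L)
  expect_true(fin$agreement)

  x2 <- make_blobs(2, 60, centers[c(1, 4), ], sd = 0.6, seed = 8)
  km2 <- kmeans_step1(x2, 10, n_restarts = 5, seed = 8)
  dend2 <- hierarchical_merge(km2$centers)
  fin2 <- select_final_k(dend2, dist(x2), cfg, step1_labels = km2$cluster)
  expect_equal(fin2$final_k, 2)
})

test_that("variable grouping keeps one representative per correlated block", {
  set.seed(9)
  n <- 200
  base <- rnorm(n)
  df <- make_kin_df(vcl = abs(base) * 50 + 30, lin = 50, wob = 80)
  ds <- kinematic_dataset(df)
  # VCL and VAP are exactly proportional here (lin, wob constant ratios):
  sel <- variable_group_select(ds, candidates = c("VCL", "VAP"), n_groups = 1)
  expect_length(sel, 1)

  # eight mutually (nearly) uncorrelated variables, 8 groups: all retained
  um <- as.data.frame(matrix(rnorm(n * 8), ncol = 8))
  names(um) <- KINEMATIC_VARS
  um$sample_type <- "fresh"; um$medium <- "CAP"; um$time_min <- 15
  um$replicate_id <- "R1"; um$sperm_id <- sprintf("u%03d", 1:n)
  ds2 <- list(records = um)
  class(ds2) <- "kinematic_dataset"
  expect_setequal(variable_group_select(ds2, KINEMATIC_VARS, n_groups = 8),
                  KINEMATIC_VARS)

  # mixture data: the selection spans the velocity, linearity and ALH blocks
  scn <- default_scn(n_per_condition = 200)
  g <- generate_kinematics(scn, sample_types = "frozen_thawed", seed = 10)
  sel3 <- variable_group_select(g$dataset, KINEMATIC_VARS, n_groups = 4)
  expect_length(sel3, 4)
  expect_true("VCL" %in% sel3 || "VAP" %in% sel3)
  expect_true(any(c("LIN", "STR") %in% sel3))
  expect_true("ALH" %in% sel3)
})

test_that("canonical labels order by VCL, are permutation-invariant, tie-break on ALH", {
  df <- make_kin_df(vcl = c(30, 30, 120, 120, 180, 180),
                    lin = 50, wob = 80, alh = c(1, 1, 2, 2, 5, 5))
  lab <- c("x", "x", "z", "z", "y", "y")
  canon <- canonicalize_labels(lab, df)
  expect_equal(as.character(canon$assignment),
               c("SP1", "SP1", "SP2", "SP2", "SP3", "SP3"))

  perm <- c("b", "b", "a", "a", "c", "c")
  expect_equal(as.character(canonicalize_labels(perm, df)$assignment),
               as.character(canon$assignment))

  # equal VCL: ALH decides
  df2 <- make_kin_df(vcl = c(100, 100, 100, 100), lin = 50, wob = 80,
                     alh = c(1, 1, 6, 6))
  canon2 <- canonicalize_labels(c("p", "p", "q", "q"), df2)
  expect_equal(as.character(canon2$assignment), c("SP1", "SP1", "SP2", "SP2"))
})

test_that("the two-step fit recovers the four subpopulations and their profile order", {
  scn <- default_scn(n_per_condition = 250)
  g <- generate_kinematics(scn, sample_types = "frozen_thawed", seed = 11)
  ds <- filter_motile(g$dataset)
  cfg <- clustering_config(n_restarts = 5, n_sil = 800)
  m <- suppressMessages(fit_subpopulations(ds, cfg, seed = 11))
  expect_equal(m$final_k, 4)
  truth <- ram_subpopulation_means()
  expect_true(all(abs(m$centroids[, "VCL"] - truth[, "VCL"]) /
                    truth[, "VCL"] < 0.05))
  # every recovered centroid within 2 within-component sd of its true mean
  for (v in c("VCL", "LIN", "ALH", "BCF")) {
    expect_true(all(abs(m$centroids[, v] - truth[, v]) <
                      2 * scn$component_cv * truth[, v]))
  }
  # assignments match ground truth for nearly all records
  agreement <- mean(as.character(m$assignment) == as.character(g$labels))
  expect_gt(agreement, 0.9)
})

test_that("subpopulation recovery is stable across the plausible within-component spread", {
  # component overlap grows with cv; the two-step count stays at 4 across
  # the swept range, allowing an occasional miss at the strongest overlap
  hits <- 0
  total <- 0
  for (cv in c(0.08, 0.12, 0.16, 0.20)) {
    cv_hits <- 0
    for (s in 1:4) {
      scn <- default_scn(component_cv = cv, n_per_condition = 250)
      g <- generate_kinematics(scn, sample_types = "frozen_thawed",
                               seed = 60 + s)
      ds <- filter_motile(g$dataset)
      m <- suppressMessages(fit_subpopulations(
        ds, clustering_config(n_restarts = 5, n_sil = 800), seed = s))
      cv_hits <- cv_hits + (m$final_k == 4)
    }
    expect_gte(cv_hits, 3)
    hits <- hits + cv_hits
    total <- total + 4
  }
  expect_gte(hits / total, 0.85)
})

test_that("fits are seed-deterministic and invariant to rescaling a driver variable", {
  scn <- default_scn(n_per_condition = 120)
  g <- generate_kinematics(scn, sample_types = "fresh", seed = 12)
  ds <- filter_motile(g$dataset)
  cfg <- clustering_config(k_range_step1 = 10:14, n_restarts = 3, n_sil = 500)
  m1 <- suppressMessages(fit_subpopulations(ds, cfg, seed = 13))
  m2 <- suppressMessages(fit_subpopulations(ds, cfg, seed = 13))
  expect_identical(m1$assignment, m2$assignment)
  expect_identical(m1$centroids, m2$centroids)

  ds_scaled <- ds
  ds_scaled$records$ALH <- ds_scaled$records$ALH * 1000
  m3 <- suppressMessages(fit_subpopulations(ds_scaled, cfg, seed = 13))
  expect_identical(as.character(m1$assignment), as.character(m3$assignment))
})
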