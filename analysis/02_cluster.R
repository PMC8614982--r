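#!/usr/bin/env Rscript

# Stage 2: motile filtering and the two-step subpopulation classification
# with ten-fold subsample stability, run separately per sample type (the
# classification pools all incubation times and both media within a sample
# type).
#
# Reads results/kinematics.csv (from 01_simulate.R); writes:
#   cluster_summary.csv      per-SP mean +/- across-run SEM of the eight
#                            kinematic variables (reference-table layout)
#   cluster_proportions.csv  per-condition SP proportions (mean/sd across
#                            the ten runs)
#   cluster_diagnostics.json silhouette / Gamma / merge-height curves and
#                            the selected counts, per sample type

suppressPackageStartupMessages({
  library(optparse)
  library(jsonlite)
  library(casaclust)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--in-dir", type = "character", default = "results"),
  make_option("--out", type = "character", default = "results"),
  make_option("--folds", type = "integer", default = 10L)
)))

ds_all <- read_casa_table(file.path(opts$`in-dir`, "kinematics.csv"))
cfg <- clustering_config(n_folds = opts$folds)

summaries <- list()
proportions <- list()
diagnostics <- list()
for (st in c("fresh", "frozen_thawed")) {
  ds <- ds_all
  ds$records <- ds$records[ds$records$sample_type == st, ]
  ds <- filter_motile(ds)
  message(st, ": ", nrow(ds$records), " motile records; fitting ",
          opts$folds, "-fold ensemble ...")
  t0 <- Sys.time()
  ens <- suppressMessages(tenfold_ensemble(ds, cfg, seed = opts$seed))
  ks <- vapply(ens$runs, function(r) r$model$final_k, integer(1))
  message("  final k per run: ", paste(ks, collapse = " "),
          "  (", round(as.numeric(difftime(Sys.time(), t0, units = "mins")), 1),
          " min)")

  summ <- summarize_subpopulations(ens)
  summ$sample_type <- st
  summaries[[st]] <- summ
  assign_tab <- do.call(rbind, lapply(ens$runs, function(r) {
    data.frame(sample_type = st, fold = r$fold,
               sperm_id = ds$records$sperm_id[ens$folds != r$fold],
               SP = as.character(r$model$assignment))
  }))
  write.csv(assign_tab,
            file.path(opts$out, paste0("cluster_assignments_", st, ".csv")),
            row.names = FALSE)
  prop <- ens$summary
  proportions[[st]] <- prop
  d1 <- ens$runs[[1]]$model$diagnostics
  diagnostics[[st]] <- list(final_k_per_run = ks,
                            silhouette_curve = d1$silhouette_curve,
                            gamma_curve = d1$gamma_curve,
                            height_curve = d1$height_curve,
                            candidate_gamma = d1$candidate_gamma,
                            candidate_lmethod = d1$candidate_lmethod)
}

write.csv(do.call(rbind, summaries), file.path(opts$out, "cluster_summary.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, proportions),
          file.path(opts$out, "cluster_proportions.csv"), row.names = FALSE)
write_json(diagnostics, file.path(opts$out, "cluster_diagnostics.json"),
           auto_unbox = TRUE, digits = 6, dataframe = "columns")
message("done: cluster tables written under ", opts$out)
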