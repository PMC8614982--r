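#!/usr/bin/env Rscript

# Stage 1: generate every synthetic input the downstream analyses consume.
#
# Emits, under results/:
#   kinematics.csv           per-spermatozoon CASA table (both sample types,
#                            full CAP/NC incubation design)
#   kinematics_truth.csv     ground-truth component label per spermatozoon
#   timecourse.csv           linked time-course (SP proportions + endpoints)
#   timecourse_truth.csv     link parameters (driver SP, rho, slope, noise)
#   cytometry_*.csv          event tables for the three stain panels
#
# The scenario defaults are the study conditions (4-component kinematic
# mixture, 2000 cells/condition, cv 0.12, 10k events/sample); --n-per-cond
# exists for quick exploratory runs only.

suppressPackageStartupMessages({
  library(optparse)
  library(casaclust)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results"),
  make_option("--n-per-cond", type = "integer", default = 2000L)
)))
dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)

scn <- suppressWarnings(synthetic_scenario(n_per_condition = opts$`n-per-cond`,
                                           seed = opts$seed))

message("generating kinematics (", opts$`n-per-cond`, " cells/condition) ...")
g <- generate_kinematics(scn, seed = opts$seed)
write_casa_table(g$dataset, file.path(opts$out, "kinematics.csv"))
write.csv(data.frame(sperm_id = g$dataset$records$sperm_id,
                     true_sp = g$labels),
          file.path(opts$out, "kinematics_truth.csv"), row.names = FALSE)
message("  ", nrow(g$dataset$records), " records, ",
        g$dataset$report["n_dropped"], " dropped by validation")

message("generating linked time-courses ...")
tc <- rbind(generate_linked_timecourse(scn, medium = "CAP", seed = opts$seed),
            generate_linked_timecourse(scn, medium = "NC",
                                       seed = opts$seed + 1L))
write.csv(tc, file.path(opts$out, "timecourse.csv"), row.names = FALSE)
write.csv(attr(tc, "truth"), file.path(opts$out, "timecourse_truth.csv"),
          row.names = FALSE)

message("generating cytometry event tables ...")
for (panel in c("mito", "viability", "py")) {
  ev <- generate_cytometry_events(scn, sample_type = "frozen_thawed",
                                  medium = "CAP", time_min = 15,
                                  panel = panel, seed = opts$seed)
  write.csv(ev, file.path(opts$out, paste0("cytometry_", panel, ".csv")),
            row.names = FALSE)
}
# pY baseline: the 0 min non-capacitating negative control
base <- generate_cytometry_events(scn, sample_type = "fresh", medium = "NC",
                                  time_min = 0, panel = "py",
                                  seed = opts$seed + 2L)
write.csv(base, file.path(opts$out, "cytometry_py_baseline.csv"),
          row.names = FALSE)
message("done: inputs written under ", opts$out)
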