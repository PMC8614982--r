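#!/usr/bin/env Rscript

# Stage 4: time-course statistics and the subpopulation/marker correlation
# table. Per (sample type, medium) the per-time means of every endpoint are
# compared with all-pairs contrasts and annotated with compact letters; the
# pooled Pearson correlations (all CAP times x replicates) between each SP
# proportion and each capacitation endpoint are tabulated with p < 0.01
# flags.
#
# Reads results/timecourse.csv (from 01_simulate.R); writes:
#   timecourse_means.csv   per-time means with compact-letter displays
#   correlations.csv       pooled correlation table per sample type

suppressPackageStartupMessages({
  library(optparse)
  library(casaclust)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--in-dir", type = "character", default = "results"),
  make_option("--out", type = "character", default = "results")
)))

tc <- read.csv(file.path(opts$`in-dir`, "timecourse.csv"))
endpoints <- unique(tc$endpoint)

means <- list()
for (st in unique(tc$sample_type)) {
  for (med in unique(tc$medium[tc$sample_type == st])) {
    for (ep in endpoints) {
      fit <- fit_time_model(tc, ep, st, med)
      df <- fit$means
      df$sample_type <- st
      df$medium <- med
      df$endpoint <- ep
      means[[paste(st, med, ep)]] <- df
    }
  }
}
means <- do.call(rbind, means)
write.csv(means, file.path(opts$out, "timecourse_means.csv"),
          row.names = FALSE)

cors <- do.call(rbind, lapply(c("fresh", "frozen_thawed"), function(st) {
  correlation_table(tc, st, medium = "CAP")
}))
write.csv(cors, file.path(opts$out, "correlations.csv"), row.names = FALSE)

# wide companion table: endpoints as rows, subpopulations as columns,
# significance marked with *
wide <- do.call(rbind, lapply(split(cors, list(cors$sample_type, cors$endpoint)),
                              function(cell) {
  row <- data.frame(sample_type = cell$sample_type[1],
                    endpoint = cell$endpoint[1])
  for (i in seq_len(nrow(cell))) {
    row[[toupper(sub("_prop", "", cell$SP[i]))]] <-
      sprintf("%.2f%s", cell$r[i],
              ifelse(isTRUE(cell$significant[i]), " *", ""))
  }
  row
}))
wide <- wide[order(wide$sample_type, wide$endpoint), ]
write.csv(wide, file.path(opts$out, "correlations_wide.csv"), row.names = FALSE)

message("significant (p < 0.01) pooled CAP correlations:")
sig <- cors[cors$significant & !is.na(cors$significant), ]
for (i in seq_len(nrow(sig))) {
  message(sprintf("  %-14s %-9s %-13s r = %+.2f", sig$sample_type[i],
                  sig$SP[i], sig$endpoint[i], sig$r[i]))
}
message("done: statistics written under ", opts$out)
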