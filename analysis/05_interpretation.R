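#!/usr/bin/env Rscript
# Stage 5: SRBV-adjusted interpretation of every course.
#
# Applies the deterministic rule cascade (serum-equivalence below 3 mg/dL,
# persistence while the break reading rebounds, trend monitoring after the
# flip, discharge eligibility on a monotone post-flip decline below
# 11 mg/dL) and writes one interpretation row per neonate with the full
# rationale trace.

suppressPackageStartupMessages(library(srbvkit))

measurements <- read_measurements("results/measurements.csv")
calib <- readr::read_csv("results/calibration.csv", show_col_types = FALSE)
calibrations <- setNames(
  lapply(seq_len(nrow(calib)), function(i) {
    calibration_model(calib$site_id[i], calib$coefficient[i])
  }),
  calib$site_id
)

series <- series_from_measurements(measurements, calibrations)
rvp <- lapply(series, detect_rvp)
interpretations <- batch_interpret(series, rvp, discharge_threshold = 11)

readr::write_csv(interpretations, "results/interpretations.csv")

cat(sprintf("interpreted %d courses; states:\n", nrow(interpretations)))
print(table(interpretations$state))
cat("actions:\n")
print(table(interpretations$action))
discharged <- interpretations[interpretations$action == "discharge_eligible", ]
cat(sprintf("%d courses (%.0f%%) end discharge-eligible\n",
            nrow(discharged), 100 * nrow(discharged) / nrow(interpretations)))
cat("example rationale trace:\n")
cat(strwrap(interpretations$rationale[1], width = 78, prefix = "  "), sep = "\n")
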