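#!/usr/bin/env Rscript
# Step 2 — measure the seven morphometric descriptors.
#
# Reads every mask listed in the step-1 sample sheet back from disk and
# computes area, perimeter, maximum/minimum Feret length and the three
# dimensionless shape factors (SF, EF, CF), all in mm / mm^2.

library(grainmorph)

sheet <- read.csv("results/cohort/sample_sheet.csv")
masks <- lapply(seq_len(nrow(sheet)), function(i) {
  read_mask(sheet$path[i], sheet$scale_mm_per_px[i], sheet$source_id[i])
})
morpho <- measure_masks(masks)
morpho <- merge(sheet[c("source_id", "stage", "interval")], morpho,
                by = "source_id", sort = FALSE)
write.csv(morpho, "results/morphometry.csv", row.names = FALSE)

cat(sprintf("measured %d grains\n", nrow(morpho)))
cat("\nstage means (across intervals):\n")
sm <- aggregate(morpho[c("A_mm2", "P_mm", "SF", "EF")],
                by = list(stage = morpho$stage), mean)
sm[-1] <- round(sm[-1], 3)
print(sm)
cat("\nArea and perimeter grow while the section rounds (SF up, EF down)\n")
cat("as filling advances; see results/morphometry.csv\n")
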