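#!/usr/bin/env Rscript
# Decomposition stage on the reference cohort: concatenate the subject
# trajectory records, PCA-whiten to the model order, run InfoMax ICA 20
# times and consolidate ICASSO-style, then compare the recovered
# connectivity patterns against the generative ground truth.

library(dfncentropy)

cohort <- readRDS("scratch/run/cohort.rds")
concat <- concatenate_subjects(cohort$subjects)
cat("Concatenated record: ", nrow(concat$X), " pairs x ", ncol(concat$X),
    " window samples (", length(cohort$subjects), " subjects).\n", sep = "")

dec <- ica_decompose(concat$X, m = 4, R = 20, seed = 1001)
saveRDS(dec, "scratch/run/decomposition.rds")
saveRDS(concat$index_map, "scratch/run/index_map.rds")

Vtrue <- t(sapply(cohort$truth$patterns, function(p) {
  diag(p) <- 0
  vectorize_upper(p)
}))
mt <- match_components(dec$patterns, Vtrue)

recov <- data.frame(
  true_source = 1:4,
  estimated_component = mt$perm,
  matched_abs_cor = round(mt$abs_cor, 4),
  stability = round(dec$stability[mt$perm], 4))
write.csv(recov, "results/pattern_recovery.csv", row.names = FALSE)

cat("ICASSO stability indices: ",
    paste(round(dec$stability, 3), collapse = ", "), ".\n", sep = "")
cat("Matched |correlation| with the designed patterns: ",
    paste(round(mt$abs_cor, 3), collapse = ", "),
    " (designed affected sources map to components ",
    paste(mt$perm[cohort$truth$affected_sources], collapse = " and "),
    ").\n", sep = "")
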