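#!/usr/bin/env Rscript
# Replication study: 10 independently generated cohorts under the
# reference conditions; in each, run the full chain and record whether
# exactly the designed affected sources are flagged at FDR < 0.05 and
# whether joint entropy is significantly reduced in patients.

library(dfncentropy)

n_rep <- 10
rows <- vector("list", n_rep)
for (r in seq_len(n_rep)) {
  coh <- simulate_cohort(n_subjects = 60, n_networks = 20, m = 4,
                         level = "dfnc", t_windows = 97, seed = 100 + r)
  cfg <- pipeline_config(master_seed = 100 + r,
                         decomposition = list(m = 4, R = 20),
                         stats = list(B = 2000))
  res <- analyze_cohort(coh, cfg)
  Vtrue <- t(sapply(coh$truth$patterns, function(p) {
    diag(p) <- 0
    vectorize_upper(p)
  }))
  mt <- match_components(res$decomposition$patterns, Vtrue)
  est_aff <- paste0("tfncp_", mt$perm[coh$truth$affected_sources])
  rep_ <- res$report
  fam <- rep_$variable != "joint"
  jrow <- rep_[rep_$variable == "joint", ]
  rows[[r]] <- data.frame(
    replicate = r,
    min_pattern_cor = round(min(mt$abs_cor), 3),
    affected_flagged = all(rep_$flagged[rep_$variable %in% est_aff]),
    null_clean = !any(rep_$flagged[fam & !rep_$variable %in% est_aff]),
    joint_g = round(jrow$g, 3),
    joint_p_perm = jrow$p_perm)
  cat("replicate ", r, ": pattern |cor| >= ",
      round(min(mt$abs_cor), 3),
      ", affected flagged = ", rows[[r]]$affected_flagged,
      ", nulls clean = ", rows[[r]]$null_clean,
      ", joint g = ", rows[[r]]$joint_g, "\n", sep = "")
}
out <- do.call(rbind, rows)
write.csv(out, "results/replicate_summary.csv", row.names = FALSE)
cat("\n", sum(out$affected_flagged & out$null_clean), " of ", n_rep,
    " replicates flag exactly the designed sources; ",
    sum(out$joint_p_perm < 0.05 & out$joint_g < 0), " of ", n_rep,
    " show significantly reduced patient joint entropy.\n", sep = "")
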