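#!/usr/bin/env Rscript
# Stage 3 — transport the stage-1 signature to a paired sleep-deprivation
# cohort (76 subjects scanned after typical sleep and after deprivation)
# and test the within-subject expression contrast, adjusting for sex, age
# group, and per-scan motion.
#
# Requires results/signature.tsv from analysis/01_train_signature.R.

library(connsig)
seed <- 1L
dir.create("results", showWarnings = FALSE)

sig <- read_connectome_table("results/signature.tsv")
dep <- simulate_deprivation(
  sim_config(n_subjects = 76, n_parcels = 30, n_sites = 1, seed = seed + 2L),
  deprivation_shift = 1)
co <- dep$cohort

et <- express(sig$weights, dep$X_typical)
ed <- express(sig$weights, dep$X_deprived)
ct <- deprivation_contrast(et, ed, co$sex, co$age_group,
                           co$mean_fd_typical, co$mean_fd_deprived)
cat(sprintf("expression after typical sleep: mean %.3f (SE %.3f)\n",
            ct$mean_typical, ct$se_typical))
cat(sprintf("expression after deprivation:  mean %.3f (SE %.3f)\n",
            ct$mean_deprived, ct$se_deprived))
cat(sprintf("adjusted within-subject difference: %+.3f, T = %.2f, p = %.3g (n = %d)\n",
            ct$mean_diff, ct$t, ct$p, ct$n))

write.table(data.frame(subject = co$subject_id, expr_typical = et,
                       expr_deprived = ed),
            "results/deprivation_expression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_sidecar(list(seed = seed, n = ct$n, mean_diff = ct$mean_diff,
                   t = ct$t, p = ct$p),
              "results/deprivation_summary.json")
cat("wrote results/deprivation_expression.tsv, results/deprivation_summary.json\n")
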