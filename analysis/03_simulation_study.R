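#!/usr/bin/env Rscript
# Step 3 — synthetic-trio simulation study.
#
# (a) Simulates a study-scale trio (520 loci, 600 CCGG sites) under the
#     calibrated parameters and shows the pipeline output is shaped like
#     the reference tables.
# (b) Re-estimates every generator parameter from the analysed output
#     at n = 1e5 and checks each against its 99% binomial interval.

suppressPackageStartupMessages(library(msaptrio))

out_dir <- "results/simulation"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
trio <- trio_spec("female", "male", "hybrid")

# (a) study-scale run through the file-based driver
sim <- run_simulate(run_config(out_dir = out_dir, seed = 20260928 %% 1e6))
s <- summarize_trio(reconcile_replicates(sim$aflp$matrix), trio)
cat("study-scale simulated trio (520 loci):\n")
print(s)
print(loss_rates(s))
h <- summarize_methylation(sim$msap$matrix, "hybrid")
f <- summarize_methylation(sim$msap$matrix, "female")
m <- summarize_methylation(sim$msap$matrix, "male")
res <- compare_hybrid_to_mpv(mid_parent(f, m), h)
cat(sprintf("\nsimulated methylation: parents %.1f%% / %.1f%%, hybrid %.1f%% (U total = %.2f)\n",
            f$pct_methylated, m$pct_methylated, h$pct_methylated,
            res$total$U))

# (b) large-n parameter recovery
p <- trio_sim_params(n_fragments = 1e5, n_sites = 5e4, seed = 31)
aflp <- simulate_trio_aflp(p, trio)
msap <- simulate_trio_msap(p, trio)
s2 <- summarize_trio(reconcile_replicates(aflp$matrix), trio)
rec <- recover_parameters(aflp_summary = s2,
                          msap = list(matrix = msap$matrix, trio = trio),
                          p = p)
cat("\nparameter recovery at n = 1e5 loci / 5e4 sites:\n")
print(rec, n = Inf)
write.table(as.data.frame(rec), file.path(out_dir, "recovery.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("\nFinding: %d of %d parameters recovered inside their 99%% interval;\n",
            sum(!rec$flagged), nrow(rec)),
    "the pipeline is an unbiased reader of the generative model at scale.\n",
    sep = "")
cat("Outputs written under ", out_dir, "/\n", sep = "")
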