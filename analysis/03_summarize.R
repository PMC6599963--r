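#!/usr/bin/env Rscript

# Stage 3: post-Gibbs analysis. Posterior means, SDs, 95% HPD intervals and
# Monte Carlo errors for every variance component and every derived genetic
# parameter (computed per posterior sample), plus a recovery table comparing
# the generating values with their HPD intervals.

suppressPackageStartupMessages(library(sgepig))

chain <- readRDS("scratch/desk_chain.rds")
s <- summarize_chain(chain, derived = TRUE)
write.table(format(s, digits = 4), "results/posterior_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- herd_scenario("desk")$true
tv <- sgepig:::varstate_to_row(truth)
labels <- sgepig:::sample_param_labels()
rows <- lapply(names(tv), function(v) {
  r <- s[s$parameter == labels[[v]], ]
  data.frame(parameter = labels[[v]], truth = tv[[v]], mean = r$mean,
             hpd_lower = r$hpd_lower, hpd_upper = r$hpd_upper,
             covered = tv[[v]] >= r$hpd_lower & tv[[v]] <= r$hpd_upper)
})
recov <- do.call(rbind, rows)
recov <- recov[labels[names(tv)] != "s2_e_STAY", ] # fixed at 1, not estimated
write.table(format(recov, digits = 4), "results/recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

free_var <- grepl("^s2_", recov$parameter)
cat(sprintf("variance components covered by 95%% HPD: %d of %d\n",
            sum(recov$covered[free_var]), sum(free_var)))
cat(sprintf("covariances covered by 95%% HPD: %d of %d\n",
            sum(recov$covered[!free_var]), sum(!free_var)))
show <- s[s$parameter %in% c("T2", "h2_ADG", "h2_STAY", "h2_NBA1",
                             "r_TBV.ADG_DBV.STAY", "r_TBV.ADG_DBV.NBA1"), ]
print(format(show, digits = 3), row.names = FALSE)
cat("tables in results/posterior_summary.tsv and results/recovery.tsv\n")
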