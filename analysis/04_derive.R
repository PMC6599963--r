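#!/usr/bin/env Rscript

# Stage 4: plug-in derived parameters from the reference herd's reported
# posterior means: total heritable variance, total and classical
# heritabilities, the social-variance share, and the correlations of the
# total breeding value for growth with the sow traits.

suppressPackageStartupMessages(library(sgepig))

ref <- reference_estimates()
d <- derived_params(ref$vs, ref$n_bar)
out <- data.frame(parameter = names(d), value = round(unname(d), 4))
write.table(out, "results/derived_reference.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("total heritable variance (growth): %.1f\n", d[["s2_TBV"]]))
cat(sprintf("phenotypic variance (growth): %.1f\n", d[["s2_P_ADG"]]))
cat(sprintf("T2 = %.2f, h2(growth) = %.2f, h2(stayability) = %.2f, h2(litter size) = %.2f\n",
            d[["T2"]], d[["h2_ADG"]], d[["h2_STAY"]], d[["h2_NBA1"]]))
cat(sprintf("social share of total heritable variance: %.0f%%\n",
            100 * variance_shares(ref$vs$C[1:2, 1:2], ref$n_bar,
                                  sigma2_TBV = ref$summary$s2_TBV)[["social"]]))
cat(sprintf("r(TBV growth, DBV stayability) = %.2f\n", d[["r_TBV.ADG_DBV.STAY"]]))
cat(sprintf("r(TBV growth, DBV litter size) = %.2f\n", d[["r_TBV.ADG_DBV.NBA1"]]))
cat("table in results/derived_reference.tsv\n")
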