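#!/usr/bin/env Rscript

# Stage 1: generate the desk-scale synthetic Yorkshire herd.
#
# Produces a 2-generation pedigree (~2,200 animals), pens of 4-14 same-sex
# pigs averaging 8.2, growth records for ~1,850 tested pigs and sow records
# (stayability to second parity, litter size at first parity) for ~740
# females, all generated under the social-effects model with the reference
# variance components as truth. Bulky data files go to scratch/; summary
# tables to results/.

suppressPackageStartupMessages(library(sgepig))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1L]]) else 42L

dir.create("results", showWarnings = FALSE)
paths <- make_benchmark_dataset(herd_scenario("desk"), "scratch/data",
                                seed = seed)
ped <- read_pedigree(paths[["pedigree"]])
rec <- load_phenotypes(paths[["phenotypes"]], ped)

cat("pedigree:", n_animals(ped), "animals,",
    sum(ped$sire == 0 & ped$dam == 0), "founders\n")
tab <- cross_tabulate_traits(rec)
print(tab)
adg <- rec$adg[!is.na(rec$adg)]
cat(sprintf("growth: mean %.1f g/d, sd %.1f (targets 802, 93)\n",
            mean(adg), sd(adg)))
stay <- rec$stay[!is.na(rec$stay)]
cat(sprintf("stayability: mean code %.2f, survival %.3f (target 0.85)\n",
            mean(stay), mean(stay == 2)))
nba <- rec$nba1[!is.na(rec$nba1)]
cat(sprintf("litter size: mean %.2f, sd %.2f (targets 10.38, 2.84)\n",
            mean(nba), sd(nba)))

write.table(as.data.frame(tab), "results/trait_overlap.tsv", sep = "\t",
            quote = FALSE)
cat("data bundle in scratch/data; overlap table in results/trait_overlap.tsv\n")
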