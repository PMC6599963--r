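#!/usr/bin/env Rscript

# Stage 2: fit the multi-trait social-effects linear-threshold model to the
# simulated herd by Gibbs sampling (20,000 rounds, 10,000 burn-in, thinning
# 10 -> 1,000 stored samples; a desk-scale shrinkage of the reference
# protocol of 1.2M rounds / 600k burn-in / thinning 100).

suppressPackageStartupMessages(library(sgepig))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1L]]) else 1L

ped <- read_pedigree("scratch/data/pedigree.tsv")
rec <- load_phenotypes("scratch/data/phenotypes.tsv", ped)
truth <- yaml::read_yaml("scratch/data/truth.yaml")
groups <- build_groups(rec, n_bar = truth$n_bar)
sys <- assemble_system(rec, groups, ped)
print(sys)

t0 <- Sys.time()
chain <- run_gibbs(sys, n_iter = 20000L, burnin = 10000L, thin = 10L,
                   seed = seed, verbose = TRUE)
cat("sampling took", format(Sys.time() - t0), "\n")
saveRDS(chain, "scratch/desk_chain.rds")
cat("chain (", nrow(chain$samples), "stored samples) in scratch/desk_chain.rds\n")
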