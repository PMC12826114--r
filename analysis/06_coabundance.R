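#!/usr/bin/env Rscript
## Step 6 — co-abundance network and prevalence.
##
## Runs SparCC-style basis-correlation inference on the compositional count
## matrix, assesses significance with the 1,000-iteration permutation
## bootstrap, retains edges at p < 0.001, and summarises per-family prevalence.

source("analysis/00_common.R")

counts_df <- read.delim(file.path(DATA_DIR, "abundance_counts.tsv"),
                        check.names = FALSE)
counts <- as.matrix(counts_df[, -1])
rownames(counts) <- counts_df$genome_id
fams <- read.delim(file.path(RESULTS, "families.tsv"))
cfg <- jumbo_config()

message("estimating SparCC correlations (", cfg$sparcc_iterations,
        " estimation iterations) ...")
rho <- sparcc_correlations(counts, cfg, seed = STUDY_SEED)
message("bootstrap significance (", cfg$n_bootstrap, " iterations) ...")
p <- bootstrap_pvalues(counts, rho, cfg, seed = STUDY_SEED)
net <- build_coabundance_network(rho, p, cfg)
tsv(net$pairs, "coabundance_edges")
message(sprintf("retained %d edges at p < %g: %d positive, %d negative",
                nrow(net$pairs), cfg$p_cutoff, net$n_positive, net$n_negative))

## prevalence: treat the count matrix as the zero-ruled abundance surrogate
prev <- prevalence_summary(counts, fams)
tsv(prev, "prevalence")
top <- prev[prev$country == "overall", ]
top <- top[order(-top$prevalence_pct), ][1:min(3, nrow(top)), ]
message("most prevalent families: ",
        paste(sprintf("%s (%.2f%%)", top$family, top$prevalence_pct),
              collapse = ", "))
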