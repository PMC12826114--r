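#!/usr/bin/env Rscript
## Step 4 — CRISPR spacer interaction network.
##
## Detects repeat-spacer arrays in every genome, matches each spacer against
## every other genome under the <= 1 mismatch / >= 95% coverage rule, and
## builds the directed phage-phage and phage-host network with mutual-targeting
## and competitive-pair classification.

source("analysis/00_common.R")

genomes <- read_fasta(file.path(DATA_DIR, "community.fasta"))
disc <- read.delim(file.path(RESULTS, "discovery.tsv"))
hosts <- read_host_table(file.path(DATA_DIR, "host_predictions.tsv"))
phages <- disc$genome_id[disc$retained]
cfg <- jumbo_config()

arrays <- list()
for (g in names(genomes)) {
  arrays <- c(arrays, detect_crispr_arrays(genomes[[g]], g, cfg))
}
message(sprintf("detected %d arrays across %d genomes", length(arrays),
                length(unique(vapply(arrays, `[[`, "", "genome_id")))))
matches <- match_spacers(arrays, genomes, cfg)
tsv(matches, "spacer_matches")

net <- build_interaction_network(matches, phages, hosts)
tsv(net$phage_phage_edges, "phage_phage_edges")
tsv(net$phage_host_edges, "phage_host_edges")
tsv(net$mutual_pairs, "mutual_pairs")
tsv(net$competitive_pairs, "competitive_pairs")
s <- network_summary(net)
tsv(s, "network_summary")
message(sprintf(
  "pairs: %d phage-phage + %d phage-host = %d; mutual %d (%.2f%%), competitive %d (%.2f%% of total)",
  s$phage_phage_pairs, s$phage_host_pairs, s$total_pairs,
  s$mutual_pairs, s$mutual_pct_of_phage_phage,
  s$competitive_pairs, s$competitive_pct_of_total))
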