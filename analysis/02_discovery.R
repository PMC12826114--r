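#!/usr/bin/env Rscript
## Step 2 — jumbo phage discovery.
##
## Reads the simulated community back from disk (exactly as a real analysis
## would read assembled contigs and their annotations), derives spacer evidence
## from CRISPR arrays found in non-viral genomes, applies the keyword/exclusion
## rule, the BUSCO-ratio filter and the > 200 kb size gate, and reports what was
## kept and why anything was removed.

source("analysis/00_common.R")

genomes <- read_fasta(file.path(DATA_DIR, "community.fasta"))
annotations <- read_annotation_table(file.path(DATA_DIR, "annotations.tsv"))
cfg <- jumbo_config()

## spacer evidence: arrays detected in genomes that are not keyword-positive
arrays <- list()
for (g in names(genomes)) {
  arrays <- c(arrays, detect_crispr_arrays(genomes[[g]], g, cfg))
}
matches <- match_spacers(arrays, genomes, cfg)
kw <- tolower(cfg$virus_keywords)
kw_pos <- vapply(names(genomes), function(g) {
  p <- tolower(annotations$product_text[annotations$genome_id == g])
  sum(vapply(p, function(x) any(vapply(kw, grepl, TRUE, x = x, fixed = TRUE)), TRUE)) >=
    cfg$min_keyword_genes
}, TRUE)
evidence <- setNames(names(genomes) %in%
  matches$target_genome[matches$source_genome %in% names(genomes)[!kw_pos]],
  names(genomes))

disc <- discover_phages(genomes, annotations, evidence, cfg)
tsv(disc, "discovery")

message(sprintf("retained %d of %d genomes as jumbo phages",
                sum(disc$retained), nrow(disc)))
print(table(removal = disc$removal_reason[!disc$retained]))
message(sprintf("BUSCO ratios: phage max %.4f | contaminant min %.4f (cut %.3f)",
                max(disc$busco_ratio[disc$retained]),
                min(disc$busco_ratio[!disc$retained]), cfg$busco_max_ratio))
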