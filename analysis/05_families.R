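#!/usr/bin/env Rscript
## Step 5 — novel family demarcation.
##
## Computes pairwise shared orthologue fractions (reciprocal best hits at
## E <= 1e-5, identity >= 30%, coverage >= 50% of the shorter protein), builds
## the whole-proteome neighbor-joining tree, and demarcates families by the
## dual criterion: genomes belong to different families when their patristic
## distance is >= 0.05 AND they share < 10% of orthologous proteins.

source("analysis/00_common.R")

annotations <- read_annotation_table(file.path(DATA_DIR, "annotations.tsv"))
disc <- read.delim(file.path(RESULTS, "discovery.tsv"))
phages <- disc$genome_id[disc$retained]
cfg <- jumbo_config()

proteomes <- lapply(phages, function(g) annotations$protein[annotations$genome_id == g])
names(proteomes) <- phages

message("computing pairwise orthologue fractions for ", length(proteomes),
        " proteomes ...")
cmp <- proteome_comparison(proteomes, cfg)
tsv(data.frame(genome_id = rownames(cmp$shared_fraction),
               round(cmp$shared_fraction, 4), check.names = FALSE),
    "shared_fraction_matrix")

tree <- build_tree(cmp$distance)
writeLines(tree$newick, file.path(RESULTS, "proteomic_tree.nwk"))
message("  wrote ", file.path(RESULTS, "proteomic_tree.nwk"))

fams <- demarcate_families(tree, cmp, cfg)
tsv(fams, "families")
sizes <- sort(table(fams$family), decreasing = TRUE)
message(sprintf("%d families demarcated; sizes: %s", length(sizes),
                paste(sizes, collapse = ", ")))
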