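#!/usr/bin/env Rscript
## Step 1 — simulate the study community.
##
## Builds the reference synthetic community with every planted signal the
## pipeline must detect (20 jumbo phages of which two carry alternative genetic
## codes and one carries crAss marker proteins, 5 bacterial contaminants,
## 10 planted spacer edges of which two are 2-mismatch negatives, 3 proteome
## families, 4 planted co-abundance correlations) and writes the community and
## its ground truth under results/data/.

source("analysis/00_common.R")

message("simulating study community (seed ", STUDY_SEED, ")")
st <- synthesize_study_community(seed = STUDY_SEED)

write_fasta(st$genomes, file.path(DATA_DIR, "community.fasta"))
write_annotation_table(st$annotations, file.path(DATA_DIR, "annotations.tsv"))
write.table(st$host_predictions, file.path(DATA_DIR, "host_predictions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(genome_id = rownames(st$abundance_counts),
                       st$abundance_counts, check.names = FALSE),
            file.path(DATA_DIR, "abundance_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
if (requireNamespace("jsonlite", quietly = TRUE)) {  # truth kept as JSON
  jsonlite::write_json(
    list(labels = st$truth$labels,
         spacer_edges = st$truth$spacer_edges,
         host_evidence_edges = st$truth$host_evidence_edges,
         correlations = st$truth$correlations),
    file.path(DATA_DIR, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
}

message(sprintf("community: %d genomes (%d phage, %d contaminant), %d genes",
                length(st$genomes), sum(st$truth$labels$is_phage),
                sum(!st$truth$labels$is_phage), nrow(st$annotations)))
message("done; downstream steps read results/data/")
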