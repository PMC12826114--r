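#!/usr/bin/env Rscript
## Step 3 — genome features of the retained phages.
##
## Assigns genetic codes by comparing protein-coding density under the standard
## code 11 and the stop-reassignment codes 15/90/91 (an alternative code needs
## a >= 10% density gain), and screens every > 70 kb genome for crAss-like
## homology against the packaged marker proteins.

source("analysis/00_common.R")

genomes <- read_fasta(file.path(DATA_DIR, "community.fasta"))
disc <- read.delim(file.path(RESULTS, "discovery.tsv"))
phages <- disc$genome_id[disc$retained]
cfg <- jumbo_config()

codes <- do.call(rbind, lapply(phages, function(g) {
  a <- assign_genetic_code(genomes[[g]], cfg)
  data.frame(genome_id = g, assigned_code = a$assigned_code,
             density_11 = round(a$densities[["11"]], 4),
             density_15 = round(a$densities[["15"]], 4),
             density_90 = round(a$densities[["90"]], 4),
             density_91 = round(a$densities[["91"]], 4))
}))
tsv(codes, "genetic_codes")
message("alternative genetic codes: ",
        paste(sprintf("%s=%d", codes$genome_id[codes$assigned_code != 11],
                      codes$assigned_code[codes$assigned_code != 11]),
              collapse = ", "))

markers <- load_crass_markers()
pool <- names(genomes)[Biostrings::width(genomes) > cfg$crass_min_bp]
crass <- do.call(rbind, lapply(pool, function(g) {
  cbind(data.frame(genome_id = g), crass_classify(genomes[[g]], markers, NULL, cfg))
}))
tsv(crass, "crass_calls")
message(sprintf("crAss-like genomes: %d of %d screened (gate > %d kb)",
                sum(crass$is_crass), nrow(crass), cfg$crass_min_bp %/% 1000))
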