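#' Assemble the reference synthetic study community
#'
#' The fixed study conditions used throughout the package's end-to-end
#' validation: 20 phage genomes (201-300 kb) and 5 contaminant genomes; the
#' first two phages carry alternative genetic codes 15 and 90; the third
#' carries the crAss marker proteins in frame; phage proteomes are planted with
#' 3 family structures (7/7/6 genomes, within-family sharing 0.6, between 0);
#' 10 directed spacer edges are planted among the phages (4 with 0 mismatches,
#' 4 with 1, and 2 negatives with 2 mismatches that must not be recovered); and
#' a 20-taxon x 200-sample compositional abundance matrix carries 4 planted
#' log-scale correlations (3 positive, 1 negative).
#'
#' @param seed integer seed controlling every random draw.
#' @param config a [jumbo_config()] list.
#' @return A list: `genomes`, `annotations`, `host_predictions`,
#'   `abundance_counts`, and `truth` (labels, family truth, planted spacer
#'   edges, host-evidence edges, planted correlations).
#' @export
synthesize_study_community <- function(seed = 1L, config = jumbo_config()) {
  fams <- generate_proteome_families(c(7L, 7L, 6L), within = 0.6, between = 0,
                                     proteome_size = 25L, seed = seed)
  comm <- generate_community(20L, 5L, seed = seed, config = config,
                             alt_codes = c(15L, 90L), n_crass = 1L,
                             phage_proteomes = fams$proteomes)
  phages <- names(comm$genomes)[1:20]
  edge_spec <- data.frame(
    source     = phages[c(4, 5, 6, 8, 10, 12, 14, 16, 18, 19)],
    target     = phages[c(5, 4, 7, 9, 11, 13, 15, 17, 19, 20)],
    n_spacers  = 1L,
    mismatches = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L),
    stringsAsFactors = FALSE)
  planted <- plant_crispr_targeting(comm$genomes, edge_spec, seed = seed,
                                    config = config)
  ab <- generate_abundance_matrix(20L, 200L,
                                  data.frame(i = c(1L, 3L, 5L, 7L),
                                             j = c(2L, 4L, 6L, 8L),
                                             sign = c("+", "+", "+", "-"),
                                             stringsAsFactors = FALSE),
                                  seed = seed)
  counts <- ab$counts
  rownames(counts) <- phages
  truth <- comm$truth
  truth$labels$family_planted <- c(fams$truth$family_planted,
                                   rep(NA_character_, 5))
  truth$spacer_edges <- planted$truth$spacer_edges
  truth$correlations <- ab$truth
  truth$latent <- ab$latent
  list(genomes = planted$genomes,
       annotations = comm$annotations,
       host_predictions = comm$host_predictions,
       abundance_counts = counts,
       truth = truth)
}

#' Score pipeline recovery of planted signals
#'
#' Compares a [run_pipeline()] report against the ground truth of
#' [synthesize_study_community()], returning precision and recall of the phage
#' calls, spacer edges (planted edges with <= 1 mismatch are positives; the
#' 2-mismatch plants must stay unrecovered), host-evidence edges, genetic-code
#' assignments, crAss flags, family partition agreement, and the signed
#' co-abundance edges.
#'
#' @param report a `jumbo_report` from [run_pipeline()].
#' @param truth the `truth` element of [synthesize_study_community()].
#' @return Named list of precision/recall/accuracy values in `[0, 1]`.
#' @export
evaluate_recovery <- function(report, truth) {
  lab <- truth$labels
  pr <- function(pred, pos) {
    list(precision = if (length(pred)) mean(pred %in% pos) else 1,
         recall = if (length(pos)) mean(pos %in% pred) else 1)
  }
  ## phage labels
  called <- report$discovery$genome_id[report$discovery$retained]
  phage_pr <- pr(called, lab$genome_id[lab$is_phage])
  ## genetic codes
  codes <- report$genetic_codes
  code_truth <- lab$genetic_code_planted[match(codes$genome_id, lab$genome_id)]
  code_acc <- mean(codes$assigned_code == code_truth)
  ## crAss
  crass <- report$crass
  crass_truth <- lab$is_crass[match(crass$genome_id, lab$genome_id)]
  crass_acc <- mean(crass$is_crass == crass_truth)
  ## spacer edges (directed phage-phage)
  planted <- truth$spacer_edges
  planted_pp <- planted[planted$source %in% lab$genome_id[lab$is_phage] &
                        planted$target %in% lab$genome_id[lab$is_phage], ,
                        drop = FALSE]
  pos_edges <- unique(paste(planted_pp$source[planted_pp$mismatches <= 1],
                            planted_pp$target[planted_pp$mismatches <= 1]))
  neg_edges <- unique(paste(planted_pp$source[planted_pp$mismatches > 1],
                            planted_pp$target[planted_pp$mismatches > 1]))
  got_edges <- paste(report$network$phage_phage_edges$source,
                     report$network$phage_phage_edges$target)
  edge_pr <- pr(got_edges, pos_edges)
  neg_recovered <- mean(neg_edges %in% got_edges)
  ## host-evidence edges
  hev <- truth$host_evidence_edges
  host_pos <- unique(paste(hev$source, hev$target))
  got_host <- paste(report$network$phage_host_edges$source,
                    report$network$phage_host_edges$target)
  host_pr <- pr(got_host, host_pos)
  ## families: exact partition agreement over genomes with planted families
  fam_ok <- NA_real_
  if (!is.null(report$families)) {
    fam <- report$families
    pl <- lab[!is.na(lab$family_planted), c("genome_id", "family_planted")]
    m <- merge(fam, pl, by = "genome_id")
    fam_ok <- as.numeric(partition_identical(m$family, m$family_planted) &&
                         nrow(m) == nrow(pl))
  }
  ## co-abundance signed edges
  co_pr <- list(precision = NA_real_, recall = NA_real_)
  sign_ok <- NA_real_
  if (!is.null(report$coabundance)) {
    ids <- rownames(report$rho)
    want <- truth$correlations
    want_key <- paste(pmin(ids[want$i], ids[want$j]),
                      pmax(ids[want$i], ids[want$j]))
    got <- report$coabundance$pairs
    got_key <- paste(pmin(got$i, got$j), pmax(got$i, got$j))
    co_pr <- pr(got_key, want_key)
    mi <- match(want_key, got_key)
    sign_ok <- mean(ifelse(want$sign_num > 0, "positive", "negative") ==
                    got$sign[mi], na.rm = TRUE)
  }
  list(phage_precision = phage_pr$precision, phage_recall = phage_pr$recall,
       code_accuracy = code_acc, crass_accuracy = crass_acc,
       spacer_edge_precision = edge_pr$precision,
       spacer_edge_recall = edge_pr$recall,
       spacer_negative_leakage = neg_recovered,
       host_edge_precision = host_pr$precision,
       host_edge_recall = host_pr$recall,
       family_partition_exact = fam_ok,
       coabundance_precision = co_pr$precision,
       coabundance_recall = co_pr$recall,
       coabundance_sign_accuracy = sign_ok)
}

## do two label vectors induce the same partition?
partition_identical <- function(a, b) {
  ta <- split(seq_along(a), a)
  tb <- split(seq_along(b), b)
  setequal(lapply(ta, sort), lapply(tb, sort))
}
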