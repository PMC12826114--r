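#' Classify a genome as crAss-like
#'
#' Genomes exceeding 70 kb are classified crAss-like if they meet either of two
#' homology criteria against the prototypical crAssphage: (1) a translated
#' (BLASTx-like) hit with E-value < 1e-10 to the crAssphage polymerase or
#' terminase marker protein, or (2) >= 95% nucleotide identity over >= 80% of
#' the genome length against the reference genome. Criterion 2 is realised as a
#' deterministic fragment-based ANI approximation: the query is cut into
#' 1,000-nt fragments, each fragment is placed on the reference by ungapped
#' matching, and a fragment counts as aligned at >= 95% identity; the genome
#' passes when >= 80% of its fragments align.
#'
#' The packaged marker FASTA (`inst/extdata/crass_markers_synthetic.faa`) holds
#' synthetic stand-in markers for testing; real analyses should supply the
#' crAssphage UGP_018 polymerase and UGP_092 terminase sequences.
#'
#' @param genome the query genome (DNAString/DNAStringSet of 1/character).
#' @param marker_proteins named [Biostrings::AAStringSet] with elements
#'   `polymerase` and `terminase` (or any two markers; names are reported).
#' @param reference_genome optional reference genome for criterion 2.
#' @param config a [jumbo_config()] list.
#' @return A one-row data.frame: marker hit flags, best E-value, nucleotide
#'   identity and aligned fraction (NA when criterion 2 was not evaluated),
#'   `is_crass`, and a `reason` string (`"size"` for the <= 70 kb gate).
#' @export
crass_classify <- function(genome, marker_proteins, reference_genome = NULL,
                           config = jumbo_config()) {
  g <- as_dna_string(genome)
  L <- length(g)
  res <- data.frame(hit_polymerase = FALSE, hit_terminase = FALSE,
                    best_evalue = Inf, nt_identity = NA_real_,
                    aligned_fraction = NA_real_, is_crass = FALSE,
                    reason = "", stringsAsFactors = FALSE)
  if (L <= config$crass_min_bp) {
    res$reason <- "size"
    return(res)
  }
  ## criterion 1: translated marker homology
  hits <- logical(length(marker_proteins))
  evals <- numeric(length(marker_proteins))
  for (i in seq_along(marker_proteins)) {
    ts <- translated_search(g, marker_proteins[[i]], config)
    evals[i] <- ts$evalue
    hits[i] <- ts$evalue < config$crass_max_evalue
  }
  nm <- names(marker_proteins)
  res$hit_polymerase <- any(hits[grepl("polymerase", nm, ignore.case = TRUE)])
  res$hit_terminase <- any(hits[grepl("terminase", nm, ignore.case = TRUE)])
  res$best_evalue <- min(evals)
  crit1 <- any(hits)
  ## criterion 2: fragment-based nucleotide identity vs the reference
  crit2 <- FALSE
  if (!is.null(reference_genome)) {
    ani <- fragment_identity(g, as_dna_string(reference_genome), config)
    res$nt_identity <- ani$identity
    res$aligned_fraction <- ani$aligned_fraction
    crit2 <- ani$aligned_fraction >= config$crass_min_aligned
  }
  res$is_crass <- crit1 || crit2
  if (!res$is_crass) res$reason <- "no_homology"
  res
}

## Fragment-based ANI surrogate: cut the query into fixed-size fragments and
## place each on the reference (either strand) by ungapped matching allowing up
## to (1 - min_identity) substitutions. aligned_fraction uses the query as the
## denominator (the comparison is therefore asymmetric in genome/reference).
fragment_identity <- function(query, reference, config = jumbo_config()) {
  fl <- config$crass_fragment_nt
  L <- length(query)
  starts <- seq(1L, L, by = fl)
  starts <- starts[starts + fl - 1L <= L | starts == 1L]
  n_frag <- length(starts)
  max_mm_frac <- 1 - config$crass_min_identity
  idents <- numeric(0)
  aligned <- 0L
  ref_rc <- reverseComplement(reference)
  for (st in starts) {
    en <- min(st + fl - 1L, L)
    frag <- subseq(query, st, en)
    w <- length(frag)
    max_mm <- floor(max_mm_frac * w)
    best_mm <- Inf
    for (ref in list(reference, ref_rc)) {
      m <- matchPattern(frag, ref, max.mismatch = max_mm, with.indels = FALSE)
      if (length(m)) {
        mm <- vapply(seq_along(m), function(k) {
          hit <- as.character(m[[k]])
          fr <- as.character(frag)
          sum(strsplit(hit, "")[[1]] != strsplit(fr, "")[[1]] |
                strsplit(hit, "")[[1]] == "N" | strsplit(fr, "")[[1]] == "N")
        }, numeric(1))
        best_mm <- min(best_mm, min(mm))
      }
      if (best_mm == 0) break
    }
    if (is.finite(best_mm) && best_mm <= max_mm) {
      aligned <- aligned + 1L
      idents <- c(idents, 1 - best_mm / w)
    }
  }
  list(identity = if (length(idents)) mean(idents) else 0,
       aligned_fraction = aligned / n_frag)
}
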