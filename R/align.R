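## Protein local-alignment utilities shared by the crAss marker search and the
## orthologue detector. Alignments use Smith-Waterman with BLOSUM62
## (Biostrings::pairwiseAlignment); significance uses ungapped Karlin-Altschul
## statistics (lambda = 0.318, K = 0.13), a deliberate reproducible
## approximation for gapped scores.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Karlin-Altschul E-value for an ungapped local alignment score
#'
#' @param score raw alignment score.
#' @param m,n effective lengths of the two sequences.
#' @param frames multiplier for translated searches (6 for a six-frame scan).
#' @param config a [jumbo_config()] list supplying `ka_lambda` and `ka_k`.
#' @return The expected number of chance alignments with at least this score.
#' @export
ka_evalue <- function(score, m, n, frames = 1, config = jumbo_config()) {
  config$ka_k * m * n * frames * exp(-config$ka_lambda * score)
}

#' Bit score from a raw alignment score (ungapped Karlin-Altschul)
#' @inheritParams ka_evalue
#' @return Normalised bit score.
#' @export
ka_bits <- function(score, config = jumbo_config()) {
  (config$ka_lambda * score - log(config$ka_k)) / log(2)
}

## raw SW score of a protein aligned to itself = sum of diagonal BLOSUM62 terms
self_alignment_score <- function(protein) {
  aa <- strsplit(as.character(protein), "")[[1]]
  B <- blosum62()
  aa[!aa %in% rownames(B)] <- "X"
  sum(B[cbind(aa, aa)])
}

## score matrix of all proteins in `a` vs all in `b` (rows = a, cols = b).
## Pairs sharing no exact `aa_seed_word`-mer are skipped (score 0), the same
## word-seeding shortcut BLAST uses; homologues above the identity thresholds
## used here always share words.
protein_score_matrix <- function(a, b, config = jumbo_config()) {
  a <- AAStringSet(a); b <- AAStringSet(b)
  S <- matrix(0, length(a), length(b))
  k <- config$aa_seed_word
  kmer_set <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, seq_len(n - k + 1L), seq(k, n)))
  }
  kb <- lapply(as.character(b), kmer_set)
  idx_b <- rep(seq_along(kb), lengths(kb))
  words_b <- unlist(kb)
  for (i in seq_along(a)) {
    cand <- sort(unique(idx_b[words_b %in% kmer_set(as.character(a[[i]]))]))
    if (!length(cand)) next
    ## SW scores are symmetric in the two sequences
    S[i, cand] <- pairwiseAlignment(b[cand], a[[i]], type = "local",
                                    substitutionMatrix = blosum62(),
                                    gapOpening = config$gap_opening,
                                    gapExtension = config$gap_extension,
                                    scoreOnly = TRUE)
  }
  S
}

## full local alignment of one protein pair: score, identity, coverage of the
## shorter protein
protein_alignment_stats <- function(pa, pb, config = jumbo_config()) {
  aln <- pairwiseAlignment(AAString(pa), AAString(pb), type = "local",
                           substitutionMatrix = blosum62(),
                           gapOpening = config$gap_opening,
                           gapExtension = config$gap_extension)
  span_a <- Biostrings::width(Biostrings::pattern(aln))
  span_b <- Biostrings::width(Biostrings::subject(aln))
  shorter <- min(nchar(pa), nchar(pb))
  cov <- (if (nchar(pa) <= nchar(pb)) span_a else span_b) / shorter
  list(score = Biostrings::score(aln),
       identity = Biostrings::pid(aln, type = "PID1") / 100,
       coverage = cov)
}

## positions in `text` whose `word`-length substring occurs in `query`
## (exact amino-acid word seeding, BLAST-style)
seed_positions <- function(text, query_words, word) {
  n <- nchar(text)
  if (n < word) return(integer())
  kmers <- substring(text, seq_len(n - word + 1L), seq(word, n))
  which(kmers %in% query_words)
}

## Seeded translated search of a protein marker against a nucleotide genome:
## translate all six frames, seed with exact `word`-aa matches, extend each
## seed by Smith-Waterman in a window around it. Returns the best raw score.
translated_search <- function(genome, marker, config = jumbo_config()) {
  g <- as_dna_string(genome)
  L <- length(g)
  marker <- as.character(marker)
  mlen <- nchar(marker)
  word <- config$aa_seed_word
  qw <- unique(substring(marker, seq_len(max(mlen - word + 1L, 1L)),
                         seq(word, max(mlen, word))))
  best <- 0
  for (strand in c("+", "-")) {
    s <- if (strand == "+") g else reverseComplement(g)
    for (frame in 0:2) {
      end <- L - (L - frame) %% 3L
      if (end - frame < 3L) next
      tr <- suppressWarnings(translate(subseq(s, frame + 1L, end),
                                       if.fuzzy.codon = "X"))
      txt <- as.character(tr)
      txt <- gsub("*", "X", txt, fixed = TRUE)  # stops never align
      seeds <- seed_positions(txt, qw, word)
      if (!length(seeds)) next
      ## merge nearby seeds into windows, then extend once per window
      groups <- cumsum(c(TRUE, diff(seeds) > mlen))
      for (grp in split(seeds, groups)) {
        lo <- max(1L, min(grp) - mlen)
        hi <- min(nchar(txt), max(grp) + 2L * mlen)
        sc <- pairwiseAlignment(AAString(marker),
                                AAString(substr(txt, lo, hi)),
                                type = "local",
                                substitutionMatrix = blosum62(),
                                gapOpening = config$gap_opening,
                                gapExtension = config$gap_extension,
                                scoreOnly = TRUE)
        if (sc > best) best <- sc
      }
    }
  }
  list(score = best,
       evalue = if (best > 0) ka_evalue(best, L, mlen, frames = 6, config = config) else Inf)
}
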