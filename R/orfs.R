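GENETIC_CODES <- c(11L, 15L, 90L, 91L)

## stop-codon set per coding scheme: the alternative codes reassign one of the
## standard stops to an amino acid (15: TAG, 90: TAA, 91: TGA)
orf_stop_codons <- function(code) {
  switch(as.character(code),
         "11" = c("TAA", "TAG", "TGA"),
         "15" = c("TAA", "TGA"),
         "90" = c("TAG", "TGA"),
         "91" = c("TAA", "TAG"),
         stop("unknown genetic code: ", code))
}

as_dna_string <- function(genome) {
  if (inherits(genome, "DNAString")) return(genome)
  if (inherits(genome, "DNAStringSet")) {
    stopifnot(length(genome) == 1L)
    return(genome[[1]])
  }
  DNAString(genome)
}

codon_positions <- function(subject, codons) {
  pos <- lapply(codons, function(cd) Biostrings::start(matchPattern(cd, subject)))
  sort(unique(unlist(pos)))
}

#' Find open reading frames under a genetic code
#'
#' Six-frame maximal-ORF scan: an ORF runs from a start codon (ATG/GTG/TTG) to
#' the next in-frame stop codon (inclusive), where the stop set is
#' \{TAA, TAG, TGA\} minus the codon reassigned by the code (code 15 removes
#' TAG, 90 removes TAA, 91 removes TGA). Spans shorter than `orf_min_nt`
#' (default 90 nt) or lacking a terminating stop are discarded. The coded
#' fraction is the width of the union of all qualifying ORF spans on both
#' strands, projected to genome coordinates, divided by genome length.
#'
#' @param genome a genome sequence (DNAString/DNAStringSet of 1/character).
#' @param code genetic code, one of 11, 15, 90, 91.
#' @param config a [jumbo_config()] list.
#' @return A list with `code`, `orfs` (data.frame of start, end, strand,
#'   frame) and `coded_fraction`.
#' @export
find_orfs <- function(genome, code = 11L, config = jumbo_config()) {
  code <- as.integer(code)
  if (!code %in% GENETIC_CODES) stop("unknown genetic code: ", code)
  g <- as_dna_string(genome)
  L <- length(g)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      stringsAsFactors = FALSE)
  if (L < config$orf_min_nt) {
    return(list(code = code, orfs = empty, coded_fraction = 0))
  }
  stops <- orf_stop_codons(code)
  starts <- config$orf_start_codons
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") g else reverseComplement(g)
    start_pos <- codon_positions(s, starts)
    stop_pos <- codon_positions(s, stops)
    for (frame in 0:2) {
      st <- start_pos[(start_pos - 1L) %% 3L == frame]
      sp <- stop_pos[(stop_pos - 1L) %% 3L == frame]
      if (!length(sp) || !length(st)) next
      ## for each stop, the ORF begins at the first start after the previous stop
      prev_end <- c(frame + 1L, sp + 3L)[seq_along(sp)]
      idx <- findInterval(prev_end - 0.5, st) + 1L
      ok <- idx <= length(st)
      p <- rep(NA_integer_, length(sp)); p[ok] <- st[idx[ok]]
      orf_end <- sp + 2L
      len <- orf_end - p + 1L
      keep <- !is.na(p) & p < sp & len >= config$orf_min_nt
      if (!any(keep)) next
      a <- p[keep]; b <- orf_end[keep]
      if (strand == "-") { tmp <- a; a <- L - b + 1L; b <- L - tmp + 1L }
      out[[length(out) + 1L]] <- data.frame(start = a, end = b,
                                            strand = strand, frame = frame,
                                            stringsAsFactors = FALSE)
    }
  }
  orfs <- if (length(out)) do.call(rbind, out) else empty
  coded <- if (nrow(orfs)) {
    sum(width(reduce(IRanges(orfs$start, orfs$end)))) / L
  } else 0
  orfs <- orfs[order(orfs$start, orfs$end), , drop = FALSE]
  rownames(orfs) <- NULL
  list(code = code, orfs = orfs, coded_fraction = coded)
}

#' Assign a genetic code by coding-density comparison
#'
#' Computes the protein-coding density (coded fraction of [find_orfs()]) under
#' the standard code 11 and the three stop-reassignment codes 15/90/91. An
#' alternative code is assigned when its density exceeds the code-11 density by
#' at least the configured margin (default 10%); among qualifying codes the one
#' with maximal density wins. Otherwise code 11 is kept.
#'
#' @param genome a genome sequence (length >= 90 nt).
#' @param config a [jumbo_config()] list.
#' @return A list with `densities` (named by code), `assigned_code`, and
#'   `undefined` (TRUE when the code-11 density is zero and the ratio is
#'   undefined, in which case code 11 is kept with a warning flag).
#' @export
assign_genetic_code <- function(genome, config = jumbo_config()) {
  g <- as_dna_string(genome)
  if (length(g) < config$orf_min_nt) stop("genome shorter than one minimal ORF")
  dens <- vapply(GENETIC_CODES, function(cd) {
    find_orfs(g, cd, config)$coded_fraction
  }, numeric(1))
  names(dens) <- as.character(GENETIC_CODES)
  d11 <- dens[["11"]]
  if (d11 == 0) {
    return(list(densities = dens, assigned_code = 11L, undefined = TRUE))
  }
  alt <- setdiff(GENETIC_CODES, 11L)
  gains <- dens[as.character(alt)] / d11
  qual <- alt[gains >= config$code_density_margin]
  assigned <- if (length(qual)) {
    qual[which.max(dens[as.character(qual)])]
  } else 11L
  list(densities = dens, assigned_code = as.integer(assigned), undefined = FALSE)
}
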