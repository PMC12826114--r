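#' Detect CRISPR repeat-spacer arrays (CRT-style)
#'
#' Scans the genome with an exact 8-nt search window: positions whose 8-mer
#' recurs downstream at a plausible period (repeat + spacer length) seed a
#' candidate repeat, which is extended outward while the two copies agree, then
#' chained to further exact copies. A candidate is reported as an array when it
#' has at least 3 repeat copies of length 23-47 nt separated by spacers of
#' 26-50 nt. Because an exact repeat recurrence is strand-symmetric, a
#' forward-strand scan reports every array in genome coordinates.
#'
#' @param genome the genome (DNAString/DNAStringSet of 1/character).
#' @param genome_id identifier carried into the result.
#' @param config a [jumbo_config()] list.
#' @return A list of arrays sorted by start; each is a list with `genome_id`,
#'   `start`, `repeats` (character), `spacers` (character), `repeat_consensus`.
#' @export
detect_crispr_arrays <- function(genome, genome_id = "genome",
                                 config = jumbo_config()) {
  seq <- as.character(as_dna_string(genome))
  n <- nchar(seq)
  k <- config$crispr_search_window
  rep_rng <- config$crispr_repeat_range
  sp_rng <- config$crispr_spacer_range
  min_period <- rep_rng[1] + sp_rng[1]
  max_period <- rep_rng[2] + sp_rng[2]
  if (n < min_period + k) return(list())
  chars <- strsplit(seq, "")[[1]]
  kmers <- substring(seq, seq_len(n - k + 1L), seq(k, n))
  ord <- order(kmers, seq_along(kmers), method = "radix")
  pos <- seq_along(kmers)[ord]
  same <- kmers[ord][-1L] == kmers[ord][-length(ord)]
  d <- pos[-1L] - pos[-length(pos)]
  cand <- which(same & d >= min_period & d <= max_period)
  if (!length(cand)) return(list())
  anchors <- data.frame(i = pos[cand], j = pos[cand + 1L])
  anchors <- anchors[order(anchors$i), , drop = FALSE]
  g <- as_dna_string(genome)
  arrays <- list()
  masked <- integer(0)  # positions already inside an accepted array
  for (r in seq_len(nrow(anchors))) {
    i <- anchors$i[r]
    if (i %in% masked) next
    ## chain all occurrences of the anchor k-mer at plausible periods
    apos <- Biostrings::start(matchPattern(substr(seq, i, i + k - 1L), g))
    copies <- i
    repeat {  # walk right
      nxt <- apos[apos >= copies[length(copies)] + min_period &
                  apos <= copies[length(copies)] + max_period]
      if (!length(nxt)) break
      copies <- c(copies, nxt[1])
    }
    repeat {  # walk left
      prv <- apos[apos <= copies[1] - min_period & apos >= copies[1] - max_period]
      if (!length(prv)) break
      copies <- c(prv[length(prv)], copies)
    }
    if (length(copies) < config$crispr_min_repeats) next
    ## extend the repeat boundaries while ALL copies agree
    min_gap <- min(diff(copies))
    left <- 0L
    while (copies[1] - left - 1L >= 1L &&
           (left + k + 1L) <= min(rep_rng[2], min_gap - sp_rng[1]) &&
           all_equal_chars(chars, copies - left - 1L)) left <- left + 1L
    right <- k - 1L
    while (copies[length(copies)] + right + 1L <= n &&
           (left + right + 2L) <= min(rep_rng[2], min_gap - sp_rng[1]) &&
           all_equal_chars(chars, copies + right + 1L)) right <- right + 1L
    rep_len <- left + right + 1L
    if (rep_len < rep_rng[1] || rep_len > rep_rng[2]) next
    spacer_lens <- diff(copies) - rep_len
    if (any(spacer_lens < sp_rng[1] | spacer_lens > sp_rng[2])) next
    starts <- copies - left
    repeats <- substring(seq, starts, starts + rep_len - 1L)
    if (length(unique(repeats)) != 1L) next  # exact-repeat arrays only
    spacers <- substring(seq, starts[-length(starts)] + rep_len, starts[-1L] - 1L)
    arrays[[length(arrays) + 1L]] <- list(
      genome_id = genome_id,
      start = starts[1],
      repeats = repeats,
      spacers = spacers,
      repeat_consensus = repeats[1]
    )
    masked <- c(masked, seq(starts[1], starts[length(starts)] + rep_len - 1L))
  }
  arrays[order(vapply(arrays, `[[`, 0, "start"))]
}

all_equal_chars <- function(chars, idx) {
  v <- chars[idx]
  all(v == v[1])
}

#' Match CRISPR spacers against a genome collection
#'
#' Each spacer is searched on both strands of every genome other than its
#' source. A match is an ungapped full-length placement of the spacer in which
#' up to `floor(L - ceiling(0.95 L))` terminal spacer positions may be clipped,
#' leaving at most one substitution in the kept window; coverage is the kept
#' fraction of the spacer. `N` never matches any base (it counts as a
#' mismatch). Overlapping placements at the same locus are collapsed to the
#' best (max coverage, then min mismatches).
#'
#' @param arrays list of CRISPR arrays (see [detect_crispr_arrays()]).
#' @param genomes named [Biostrings::DNAStringSet].
#' @param config a [jumbo_config()] list.
#' @return A data.frame of spacer matches: `source_genome`, `array_index`,
#'   `spacer_index`, `target_genome`, `target_start`, `strand`, `mismatches`,
#'   `coverage`.
#' @export
match_spacers <- function(arrays, genomes, config = jumbo_config()) {
  out <- list()
  for (ai in seq_along(arrays)) {
    arr <- arrays[[ai]]
    for (si in seq_along(arr$spacers)) {
      spacer <- arr$spacers[si]
      L <- nchar(spacer)
      margin <- L - ceiling(config$spacer_min_coverage * L)
      for (tg in names(genomes)) {
        if (tg == arr$genome_id) next
        hits <- spacer_hits(spacer, genomes[[tg]], margin,
                            config$spacer_max_mismatch)
        if (nrow(hits)) {
          hits$source_genome <- arr$genome_id
          hits$array_index <- ai
          hits$spacer_index <- si
          hits$target_genome <- tg
          out[[length(out) + 1L]] <- hits
        }
      }
    }
  }
  if (!length(out)) return(empty_spacer_matches())
  df <- do.call(rbind, out)
  df[, c("source_genome", "array_index", "spacer_index", "target_genome",
         "target_start", "strand", "mismatches", "coverage")]
}

empty_spacer_matches <- function() {
  data.frame(source_genome = character(), array_index = integer(),
             spacer_index = integer(), target_genome = character(),
             target_start = integer(), strand = character(),
             mismatches = integer(), coverage = numeric(),
             stringsAsFactors = FALSE)
}

## all qualifying placements of one spacer on one genome (both strands)
spacer_hits <- function(spacer, genome, margin, max_mm) {
  sp_chars <- strsplit(spacer, "")[[1]]
  L <- length(sp_chars)
  glen <- length(genome)
  res <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") DNAString(spacer)
           else reverseComplement(DNAString(spacer))
    m <- matchPattern(pat, genome, max.mismatch = max_mm + margin,
                      with.indels = FALSE)
    if (!length(m)) next
    pos <- Biostrings::start(m)
    for (p in pos) {
      hit <- strsplit(as.character(subseq(genome, p, p + L - 1L)), "")[[1]]
      sp <- if (strand == "+") sp_chars else
        rev(chartr("ACGT", "TGCA", sp_chars))
      mmv <- hit != sp | hit == "N" | sp == "N"
      best <- best_clip(mmv, margin, max_mm)
      if (is.null(best)) next
      res[[length(res) + 1L]] <- data.frame(
        target_start = p, strand = strand,
        mismatches = best$mm, coverage = best$cov,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(data.frame())
  df <- do.call(rbind, res)
  ## collapse overlapping placements: best coverage, then fewest mismatches
  df <- df[order(-df$coverage, df$mismatches), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    ov <- abs(df$target_start - df$target_start[i]) < L & seq_len(nrow(df)) > i
    keep[ov] <- FALSE
  }
  df[keep, , drop = FALSE]
}

## choose terminal clipping (a from left, b from right, a + b <= margin)
## maximising coverage subject to <= max_mm mismatches in the kept window
best_clip <- function(mmv, margin, max_mm) {
  L <- length(mmv)
  best <- NULL
  for (clip in 0:margin) {
    for (a in 0:clip) {
      b <- clip - a
      mm <- sum(mmv[(a + 1L):(L - b)])
      if (mm <= max_mm) {
        cov <- (L - clip) / L
        if (is.null(best) || cov > best$cov ||
            (cov == best$cov && mm < best$mm)) {
          best <- list(mm = as.integer(mm), cov = cov)
        }
      }
    }
    if (!is.null(best)) break  # smaller clip always wins on coverage
  }
  best
}

#' Build the spacer-based interaction network
#'
#' Directed phage-phage edges (A -> B: a spacer in A matches B), phage-host
#' edges flagged by evidence direction (`host_targets_phage` when the array is
#' in the host, `phage_targets_host` otherwise), mutual pairs (phage pairs with
#' edges both ways), and competitive pairs: an unordered phage pair with at
#' least one spacer edge between them whose predicted host phylum sets
#' intersect.
#'
#' @param matches spacer-match data.frame from [match_spacers()].
#' @param phage_ids character vector of genome ids considered phage.
#' @param host_preds optional host-prediction data.frame for the phages.
#' @return A list with `phage_phage_edges`, `phage_host_edges` (data.frames
#'   with `n_spacers` multiplicity), `mutual_pairs`, `competitive_pairs`.
#' @export
build_interaction_network <- function(matches, phage_ids, host_preds = NULL) {
  m <- matches
  src_phage <- m$source_genome %in% phage_ids
  tgt_phage <- m$target_genome %in% phage_ids
  pp <- m[src_phage & tgt_phage, , drop = FALSE]
  ph <- m[xor(src_phage, tgt_phage), , drop = FALSE]
  agg_edges <- function(df, dir = NULL) {
    if (nrow(df) == 0L) {
      return(data.frame(source = character(), target = character(),
                        n_spacers = integer(), direction = character(),
                        stringsAsFactors = FALSE))
    }
    key <- paste(df$source_genome, df$target_genome, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- data.frame(source = vapply(parts, `[`, "", 1L),
                      target = vapply(parts, `[`, "", 2L),
                      n_spacers = as.integer(tab),
                      stringsAsFactors = FALSE)
    out$direction <- if (is.null(dir)) "" else dir(out)
    out <- out[order(out$source, out$target), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  pp_edges <- agg_edges(pp, function(o) "phage_targets_phage")
  ph_edges <- agg_edges(ph, function(o) {
    ifelse(o$source %in% phage_ids, "phage_targets_host", "host_targets_phage")
  })
  ## mutual: unordered phage pairs with directed edges both ways
  ekey <- paste(pp_edges$source, pp_edges$target, sep = "\r")
  rkey <- paste(pp_edges$target, pp_edges$source, sep = "\r")
  mutual_rows <- pp_edges[ekey %in% rkey & pp_edges$source < pp_edges$target, ,
                          drop = FALSE]
  mutual_pairs <- unique(data.frame(a = mutual_rows$source,
                                    b = mutual_rows$target,
                                    stringsAsFactors = FALSE))
  ## competitive: >= 1 edge either way AND shared predicted host phylum
  upairs <- unique(data.frame(a = pmin(pp_edges$source, pp_edges$target),
                              b = pmax(pp_edges$source, pp_edges$target),
                              stringsAsFactors = FALSE))
  competitive <- upairs[rep(FALSE, nrow(upairs)), , drop = FALSE]
  if (!is.null(host_preds) && nrow(upairs)) {
    phyla <- split(host_preds$host_phylum, host_preds$genome_id)
    shared <- vapply(seq_len(nrow(upairs)), function(i) {
      pa <- phyla[[upairs$a[i]]]; pb <- phyla[[upairs$b[i]]]
      length(intersect(pa, pb)) > 0
    }, TRUE)
    competitive <- upairs[shared, , drop = FALSE]
  }
  rownames(mutual_pairs) <- NULL; rownames(competitive) <- NULL
  list(phage_phage_edges = pp_edges,
       phage_host_edges = ph_edges,
       mutual_pairs = mutual_pairs,
       competitive_pairs = competitive)
}

#' Summarise an interaction network
#'
#' Pair counts use unordered pairs; because "interaction" counts in the
#' literature are ambiguous between directed edges and unordered pairs, both
#' are reported. Percentages are computed with [summarize_percent()]: mutual
#' pairs as a percent of phage-phage pairs, and competitive pairs under both
#' normalisations (percent of all pairs, which matches the published 16.94%
#' convention, and percent of phage-phage pairs).
#'
#' @param network result of [build_interaction_network()].
#' @return A one-row data.frame of counts and percentages.
#' @export
network_summary <- function(network) {
  pp <- network$phage_phage_edges
  ph <- network$phage_host_edges
  pp_pairs <- if (nrow(pp)) nrow(unique(data.frame(a = pmin(pp$source, pp$target),
                                                   b = pmax(pp$source, pp$target)))) else 0L
  ph_pairs <- if (nrow(ph)) nrow(unique(data.frame(a = pmin(ph$source, ph$target),
                                                   b = pmax(ph$source, ph$target)))) else 0L
  total <- pp_pairs + ph_pairs
  n_mutual <- nrow(network$mutual_pairs)
  n_comp <- nrow(network$competitive_pairs)
  data.frame(
    phage_phage_pairs = pp_pairs,
    phage_host_pairs = ph_pairs,
    total_pairs = total,
    phage_phage_directed_edges = nrow(pp),
    mutual_pairs = n_mutual,
    mutual_pct_of_phage_phage = if (pp_pairs > 0) summarize_percent(n_mutual, pp_pairs) else 0,
    competitive_pairs = n_comp,
    competitive_pct_of_total = if (total > 0) summarize_percent(n_comp, total) else 0,
    competitive_pct_of_phage_phage = if (pp_pairs > 0) summarize_percent(n_comp, pp_pairs) else 0,
    stringsAsFactors = FALSE
  )
}
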