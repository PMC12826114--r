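#' Score the four viral signatures of a contig
#'
#' A contig is scored on four signatures commonly combined for viral contig
#' identification: (1) presence of viral protein families (>= 10% of genes by
#' default), (2) absence of microbial protein families (<= 2% of genes),
#' (3) a viral nucleotide signature (pluggable predicate; defaults to absent
#' because no trained sequence model is shipped), and (4) a run of many
#' adjacent genes on the same strand (>= 10 by default).
#'
#' @param genome a single genome as [Biostrings::DNAString],
#'   [Biostrings::DNAStringSet] of length 1, or character string.
#' @param annotations annotation data.frame rows for this genome.
#' @param config a [jumbo_config()] list.
#' @return A one-row data.frame: `genome_id`, the four logical flags, and
#'   `n_signatures`.
#' @export
score_viral_signatures <- function(genome, annotations, config = jumbo_config()) {
  gid <- genome_id_of(genome, annotations)
  n_genes <- nrow(annotations)
  labels <- parse_hit_labels(annotations$hit_labels)
  has_viral <- FALSE; lacks_microbial <- FALSE; strand_runs <- FALSE
  if (n_genes > 0) {
    viral_frac <- mean(vapply(labels, function(v) "viral_family" %in% v, TRUE))
    microb_frac <- mean(vapply(labels, function(v) "microbial_family" %in% v, TRUE))
    has_viral <- viral_frac >= config$viral_family_min
    lacks_microbial <- microb_frac <= config$microbial_family_max
    ord <- order(annotations$start)
    runs <- rle(annotations$strand[ord])
    strand_runs <- any(runs$lengths >= config$strand_run_min)
  }
  nt_sig <- if (is.function(config$nt_signature_fun)) {
    isTRUE(config$nt_signature_fun(genome))
  } else FALSE
  data.frame(genome_id = gid,
             has_viral_families = has_viral,
             lacks_microbial_families = lacks_microbial,
             has_viral_nt_signature = nt_sig,
             has_strand_runs = strand_runs,
             n_signatures = sum(has_viral, lacks_microbial, nt_sig, strand_runs),
             stringsAsFactors = FALSE)
}

genome_id_of <- function(genome, annotations) {
  if (inherits(genome, "DNAStringSet") && !is.null(names(genome))) return(names(genome)[1])
  if (nrow(annotations) > 0) return(annotations$genome_id[1])
  "genome"
}

#' Call a genome as phage by the keyword rule
#'
#' A genome is called phage iff it carries at least `min_keyword_genes` genes
#' whose product text contains a virus-specific keyword (case-insensitive
#' substring), carries no gene with a prokaryote-specific exclusion term, and
#' has at least one CRISPR spacer match from a non-viral (bacterial/archaeal)
#' genome.
#'
#' @param genome_id genome identifier.
#' @param annotations annotation rows for this genome.
#' @param spacer_evidence logical; does any spacer from a non-phage genome
#'   match this genome?
#' @param genome_length genome length in bp (for the jumbo flag).
#' @param config a [jumbo_config()] list.
#' @return A one-row data.frame with keyword counts, the BUSCO ratio fields,
#'   `is_phage` and `is_jumbo`.
#' @export
call_phage <- function(genome_id, annotations, spacer_evidence,
                       genome_length, config = jumbo_config()) {
  products <- tolower(annotations$product_text)
  kw <- tolower(config$virus_keywords)
  ex <- tolower(config$exclusion_terms)
  gene_has_kw <- vapply(products, function(p) any(vapply(kw, grepl, TRUE, x = p, fixed = TRUE)), TRUE,
                        USE.NAMES = FALSE)
  gene_has_ex <- vapply(products, function(p) any(vapply(ex, grepl, TRUE, x = p, fixed = TRUE)), TRUE,
                        USE.NAMES = FALSE)
  n_keyword <- sum(gene_has_kw)
  has_ex <- any(gene_has_ex)
  is_phage <- n_keyword >= config$min_keyword_genes && !has_ex &&
    isTRUE(spacer_evidence)
  n_genes <- nrow(annotations)
  bus <- if (n_genes > 0) busco_filter(annotations, config) else
    list(busco_ratio = NA_real_, passes_busco = NA)
  data.frame(genome_id = genome_id,
             n_keyword_genes = n_keyword,
             has_exclusion_term = has_ex,
             has_spacer_evidence = isTRUE(spacer_evidence),
             is_phage = is_phage,
             busco_hits = sum(annotations$busco_hit),
             n_genes = n_genes,
             busco_ratio = bus$busco_ratio,
             passes_busco = bus$passes_busco,
             is_jumbo = genome_length > config$jumbo_min_bp,
             stringsAsFactors = FALSE)
}

#' BUSCO-ratio false-positive filter
#'
#' The BUSCO ratio is the fraction of a genome's predicted genes hitting
#' bacterial universal single-copy orthologs. Viral genomes sit in the 0-0.067
#' band; a putative phage is retained iff its ratio is strictly below 0.067
#' (a ratio of exactly 0.067 fails).
#'
#' @param annotations annotation rows for one genome (>= 1 gene).
#' @param config a [jumbo_config()] list.
#' @return `list(busco_ratio, passes_busco)`.
#' @export
busco_filter <- function(annotations, config = jumbo_config()) {
  n <- nrow(annotations)
  if (n == 0L) stop("BUSCO ratio undefined for a genome with zero genes")
  ratio <- sum(annotations$busco_hit) / n
  list(busco_ratio = ratio, passes_busco = ratio < config$busco_max_ratio)
}

#' Assign a lifestyle from a lysogeny score and provirus evidence
#'
#' Base classes by score: virulent (< 0.5), uncertain (0.5-0.9, closed
#' interval), temperate (> 0.9). Provirus evidence overrides the base class to
#' temperate, merging integrated-prophage detections with score-predicted
#' temperate phages.
#'
#' @param score lysogeny score in `[0, 1]`.
#' @param provirus_flag logical provirus evidence.
#' @param genome_id optional identifier carried through.
#' @param config a [jumbo_config()] list.
#' @return A one-row data.frame: `genome_id`, `score`, `provirus_flag`,
#'   `lifestyle`.
#' @export
assign_lifestyle <- function(score, provirus_flag, genome_id = NA_character_,
                             config = jumbo_config()) {
  if (is.na(score) || score < 0 || score > 1) stop("lifestyle score outside [0, 1]")
  base <- if (score < config$lifestyle_virulent_max) "virulent"
          else if (score > config$lifestyle_temperate_min) "temperate"
          else "uncertain"
  lifestyle <- if (isTRUE(provirus_flag)) "temperate" else base
  data.frame(genome_id = genome_id, score = score,
             provirus_flag = isTRUE(provirus_flag), lifestyle = lifestyle,
             stringsAsFactors = FALSE)
}

#' Classify host breadth per genome
#'
#' `generalist` iff predicted hosts span two or more distinct phyla,
#' `archaeal` iff any predicted host is archaeal, `unknown` iff there are no
#' predictions, otherwise `specialist`. A genome that is both archaeal-infecting
#' and multi-phylum is reported `archaeal` (domain takes precedence; the two
#' counts are tallied separately upstream).
#'
#' @param host_preds host-prediction data.frame (see [read_host_table()]).
#' @param genome_ids optional character vector of genomes to report (genomes
#'   without predictions are reported `unknown`).
#' @return A data.frame `genome_id`, `n_hosts`, `n_phyla`, `breadth_class`.
#' @export
classify_host_breadth <- function(host_preds, genome_ids = NULL) {
  ids <- if (is.null(genome_ids)) unique(host_preds$genome_id) else genome_ids
  out <- lapply(ids, function(g) {
    rows <- host_preds[host_preds$genome_id == g, , drop = FALSE]
    if (nrow(rows) == 0L) {
      return(data.frame(genome_id = g, n_hosts = 0L, n_phyla = 0L,
                        breadth_class = "unknown", stringsAsFactors = FALSE))
    }
    phyla <- unique(rows$host_phylum)
    cls <- if (any(rows$host_domain == "Archaea")) "archaeal"
           else if (length(phyla) >= 2L) "generalist"
           else "specialist"
    data.frame(genome_id = g, n_hosts = nrow(rows), n_phyla = length(phyla),
               breadth_class = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Percentage with half-up rounding to two decimals
#'
#' @param count numerator (0 <= count <= total).
#' @param total denominator (> 0).
#' @return `100 * count / total`, rounded half-up to 2 decimals.
#' @export
summarize_percent <- function(count, total) {
  if (any(total <= 0)) stop("summarize_percent: total must be positive")
  if (any(count < 0) || any(count > total)) stop("summarize_percent: count outside [0, total]")
  x <- 100 * count / total
  floor(x * 100 + 0.5) / 100
}

#' Run the discovery stage over a genome collection
#'
#' Applies [score_viral_signatures()], [call_phage()] and [busco_filter()] to
#' every genome and combines them with the jumbo size filter. Spacer evidence
#' is a named logical vector (typically derived from CRISPR spacer matches
#' whose source genome is not itself keyword-positive).
#'
#' @param genomes a named [Biostrings::DNAStringSet].
#' @param annotations annotation data.frame for all genomes.
#' @param spacer_evidence named logical vector by genome id (default: all TRUE,
#'   for use when external spacer databases are unavailable).
#' @param config a [jumbo_config()] list.
#' @return A data.frame, one row per genome, with the phage call, BUSCO fields,
#'   jumbo flag and final retention (`retained = is_phage & passes_busco &
#'   is_jumbo`) plus a machine-readable removal reason.
#' @export
discover_phages <- function(genomes, annotations,
                            spacer_evidence = NULL, config = jumbo_config()) {
  ids <- names(genomes)
  if (length(genomes) == 0L) {
    return(cbind(call_phage("x", empty_annotation(), TRUE, 1L, config)[0, ],
                 data.frame(retained = logical(0), removal_reason = character(0))))
  }
  if (is.null(spacer_evidence)) {
    spacer_evidence <- setNames(rep(TRUE, length(ids)), ids)
  }
  lens <- setNames(Biostrings::width(genomes), ids)
  calls <- lapply(ids, function(g) {
    ann <- annotations[annotations$genome_id == g, , drop = FALSE]
    call_phage(g, ann, isTRUE(spacer_evidence[[g]]), lens[[g]], config)
  })
  res <- do.call(rbind, calls)
  res$retained <- res$is_phage & res$is_jumbo &
    !is.na(res$passes_busco) & res$passes_busco
  res$removal_reason <- ifelse(res$retained, "",
    ifelse(!res$has_spacer_evidence & res$n_keyword_genes >= config$min_keyword_genes &
             !res$has_exclusion_term, "no_spacer_evidence",
    ifelse(res$n_keyword_genes < config$min_keyword_genes, "keyword_fail",
    ifelse(res$has_exclusion_term, "exclusion_term",
    ifelse(is.na(res$passes_busco) | !res$passes_busco, "busco_fail",
           "size_fail")))))
  res
}
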