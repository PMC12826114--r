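#' Run the full jumbo-phage analysis pipeline
#'
#' Stages, in order: discovery (viral keyword rule + BUSCO filter + jumbo size
#' gate), genome features (genetic-code assignment, crAss-like classification),
#' CRISPR network (array detection, spacer matching, interaction network),
#' families (orthologue fractions, proteomic tree, dual demarcation), and
#' co-abundance (zero-ruled abundances, SparCC correlations, bootstrap
#' significance). Spacer evidence for the discovery keyword rule is derived
#' from detected arrays whose source genome is not itself keyword-positive.
#' The crAss-like gate (> 70 kb) runs on the pre-size-filter pool, while only
#' > 200 kb genomes enter the final catalogue; both sets are reported.
#'
#' @param genomes named [Biostrings::DNAStringSet].
#' @param annotations gene annotation data.frame.
#' @param config a [jumbo_config()] list.
#' @param host_predictions optional host-prediction data.frame.
#' @param lifestyle optional lifestyle table (`genome_id, score,
#'   provirus_flag`).
#' @param abundance_counts optional taxa x samples count matrix for the
#'   co-abundance stage (alternatively supply `coverage_tracks`).
#' @param coverage_tracks optional list of coverage tracks.
#' @param crass_markers optional marker [Biostrings::AAStringSet]; defaults to
#'   the packaged synthetic markers.
#' @param crass_reference optional reference genome for the nucleotide
#'   criterion.
#' @param seed integer seed for the stochastic stages.
#' @param outdir optional directory for per-stage TSV outputs.
#' @return A `jumbo_report` list with per-stage tables and a `counts` summary.
#' @export
run_pipeline <- function(genomes, annotations, config = jumbo_config(),
                         host_predictions = NULL, lifestyle = NULL,
                         abundance_counts = NULL, coverage_tracks = NULL,
                         crass_markers = NULL, crass_reference = NULL,
                         seed = config$seed, outdir = NULL) {
  report <- list(config = config, seed = seed)
  ids <- names(genomes)
  n_input <- length(genomes)

  ## ---- CRISPR arrays & spacer matches (needed first: spacer evidence) ----
  arrays <- list()
  for (g in ids) {
    arrays <- c(arrays, detect_crispr_arrays(genomes[[g]], g, config))
  }
  matches <- match_spacers(arrays, genomes, config)

  ## spacer evidence from non-viral sources: source genome not keyword-positive
  kw_positive <- vapply(ids, function(g) {
    ann <- annotations[annotations$genome_id == g, , drop = FALSE]
    products <- tolower(ann$product_text)
    kw <- tolower(config$virus_keywords)
    sum(vapply(products, function(p) any(vapply(kw, grepl, TRUE, x = p, fixed = TRUE)),
               TRUE)) >= config$min_keyword_genes
  }, TRUE)
  evidence_sources <- ids[!kw_positive]
  spacer_evidence <- setNames(ids %in%
    unique(matches$target_genome[matches$source_genome %in% evidence_sources]),
    ids)

  ## ---- discovery ----------------------------------------------------------
  disc <- discover_phages(genomes, annotations, spacer_evidence, config)
  report$discovery <- disc
  phage_ids <- disc$genome_id[disc$retained]
  report$counts <- data.frame(stage = "discovery", input = n_input,
                              passed = length(phage_ids),
                              removed = n_input - length(phage_ids),
                              stringsAsFactors = FALSE)

  ## ---- lifestyle ----------------------------------------------------------
  if (!is.null(lifestyle)) {
    ls_rows <- lifestyle[lifestyle$genome_id %in% phage_ids, , drop = FALSE]
    report$lifestyle <- do.call(rbind, lapply(seq_len(nrow(ls_rows)), function(i) {
      assign_lifestyle(ls_rows$score[i], ls_rows$provirus_flag[i],
                       ls_rows$genome_id[i], config)
    }))
  }

  ## ---- host breadth -------------------------------------------------------
  if (!is.null(host_predictions)) {
    report$host_breadth <- classify_host_breadth(host_predictions, phage_ids)
  }

  ## ---- genome features ----------------------------------------------------
  codes <- lapply(phage_ids, function(g) {
    a <- assign_genetic_code(genomes[[g]], config)
    data.frame(genome_id = g, assigned_code = a$assigned_code,
               density_11 = a$densities[["11"]],
               density_assigned = a$densities[[as.character(a$assigned_code)]],
               stringsAsFactors = FALSE)
  })
  report$genetic_codes <- do.call(rbind, codes)
  if (is.null(crass_markers)) crass_markers <- load_crass_markers()
  ## crAss gate runs on the pre-size-filter pool (> 70 kb), catalogue is > 200 kb
  crass_pool <- ids[Biostrings::width(genomes) > config$crass_min_bp]
  crass <- lapply(crass_pool, function(g) {
    cbind(data.frame(genome_id = g, stringsAsFactors = FALSE),
          crass_classify(genomes[[g]], crass_markers, crass_reference, config))
  })
  report$crass <- do.call(rbind, crass)

  ## ---- interaction network ------------------------------------------------
  network <- build_interaction_network(matches, phage_ids, host_predictions)
  report$arrays <- arrays
  report$spacer_matches <- matches
  report$network <- network
  report$network_summary <- network_summary(network)

  ## ---- families -----------------------------------------------------------
  phage_proteomes <- lapply(phage_ids, function(g) {
    annotations$protein[annotations$genome_id == g]
  })
  names(phage_proteomes) <- phage_ids
  nonempty <- vapply(phage_proteomes, length, 1L) > 0
  if (sum(nonempty) >= 3) {
    cmp <- proteome_comparison(phage_proteomes[nonempty], config)
    tree <- build_tree(cmp$distance)
    fams <- demarcate_families(tree, cmp, config)
    report$orthologues <- cmp
    report$tree <- tree
    report$families <- fams
  }

  ## ---- co-abundance -------------------------------------------------------
  if (is.null(abundance_counts) && !is.null(coverage_tracks)) {
    am <- abundance_matrix(coverage_tracks, config)
    report$abundance <- am
    abundance_counts <- abundance_pseudo_counts(am$abundance, config)
  }
  if (!is.null(abundance_counts) && nrow(abundance_counts) >= 3) {
    rho <- sparcc_correlations(abundance_counts, config, seed = seed)
    p <- bootstrap_pvalues(abundance_counts, rho, config, seed = seed + 1L)
    report$coabundance <- build_coabundance_network(rho, p, config)
    report$rho <- rho
    report$pvalues <- p
  }

  class(report) <- c("jumbo_report", "list")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df)) {
      write.table(df, file.path(outdir, paste0(name, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  wt(report$discovery, "discovery")
  wt(report$genetic_codes, "genetic_codes")
  wt(report$crass, "crass")
  wt(report$spacer_matches, "spacer_matches")
  wt(report$network$phage_phage_edges, "phage_phage_edges")
  wt(report$network$phage_host_edges, "phage_host_edges")
  wt(report$network_summary, "network_summary")
  wt(report$families, "families")
  if (!is.null(report$coabundance)) wt(report$coabundance$pairs, "coabundance_edges")
  if (!is.null(report$tree)) writeLines(report$tree$newick,
                                        file.path(outdir, "proteomic_tree.nwk"))
  invisible(outdir)
}

#' Per-family prevalence, overall and per country
#'
#' A family is present in a sample iff any member has non-zero abundance after
#' the breadth-zeroing rule; prevalence is the percentage of samples with
#' presence ([summarize_percent()]).
#'
#' @param abundance zero-ruled abundance matrix (genomes x samples).
#' @param families data.frame `genome_id, family`.
#' @param sample_countries optional named character vector (sample -> country).
#' @return A data.frame `family, country, n_samples, n_present,
#'   prevalence_pct` with `country = "overall"` rows first.
#' @export
prevalence_summary <- function(abundance, families, sample_countries = NULL) {
  fams <- unique(families$family)
  samples <- colnames(abundance)
  groups <- list(overall = samples)
  if (!is.null(sample_countries)) {
    groups <- c(groups, split(samples, sample_countries[samples]))
  }
  out <- list()
  for (f in fams) {
    members <- families$genome_id[families$family == f]
    members <- intersect(members, rownames(abundance))
    present <- if (length(members)) {
      colSums(abundance[members, , drop = FALSE] > 0) > 0
    } else setNames(rep(FALSE, length(samples)), samples)
    for (g in names(groups)) {
      ss <- groups[[g]]
      out[[length(out) + 1L]] <- data.frame(
        family = f, country = g, n_samples = length(ss),
        n_present = sum(present[ss]),
        prevalence_pct = summarize_percent(sum(present[ss]), length(ss)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
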