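## Synthetic communities with planted, ground-truthed signals for every
## pipeline stage. Background sequence is iid uniform A/C/G/T: no stage here
## relies on realistic composition beyond stop-codon statistics. Planted
## regions are laid out in zones so later plants never clobber earlier ones:
## gene coordinate annotations occupy [1, 0.60 L], protospacers are read from
## [0.30 L, 0.60 L] of targets, and arrays/markers are written from 0.65 L
## onward (per-genome cursor in mcols()$plant_cursor).

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

## point-mutate a protein; two copies of a master stay >= 95% identical
## with overwhelming probability at the default rate
mutate_protein <- function(p, rate = 0.01) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  v <- strsplit(p, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(aa, v[i]), 1)
  paste(v, collapse = "")
}

plant_cursor <- function(genomes) {
  mc <- S4Vectors::mcols(genomes)
  if (is.null(mc$plant_cursor)) {
    S4Vectors::mcols(genomes)$plant_cursor <-
      as.integer(floor(0.65 * Biostrings::width(genomes)))
  }
  genomes
}

## overwrite a slice of genome `gid` at its plant cursor; returns updated set
write_at_cursor <- function(genomes, gid, fragment) {
  genomes <- plant_cursor(genomes)
  cur <- S4Vectors::mcols(genomes)$plant_cursor
  names(cur) <- names(genomes)
  pos <- cur[[gid]]
  L <- Biostrings::width(genomes)[names(genomes) == gid]
  if (pos + nchar(fragment) - 1L > L - 10L) {
    stop("no room left to plant in genome ", gid)
  }
  seqs <- as.character(genomes)
  substr(seqs[[gid]], pos, pos + nchar(fragment) - 1L) <- fragment
  out <- DNAStringSet(seqs)
  names(out) <- names(genomes)
  S4Vectors::mcols(out) <- S4Vectors::mcols(genomes)
  S4Vectors::mcols(out)$plant_cursor[names(out) == gid] <-
    as.integer(pos + nchar(fragment) + 50L)
  out
}

#' Generate a synthetic community with planted phage and contaminant signals
#'
#' Phage genomes are 201-300 kb of gene-structured (coding-dense) sequence
#' under the standard genetic code, with gene annotations of
#' which several (default 5) carry virus keyword product
#' text and none carry exclusion terms; contaminant genomes carry BUSCO hits on
#' 30% of genes (well above the 6.7% retention bound) and no virus keywords.
#' Each phage receives spacer evidence: contaminant ("host") genomes carry
#' CRISPR arrays whose spacers target the phages (round-robin), recorded in the
#' truth as `host_evidence_edges`. Optionally, leading phages are rebuilt as
#' stop-codon-recoded genomes (`alt_codes`) and/or carry planted crAss marker
#' proteins (`n_crass`), and phage proteomes can be supplied (e.g. from
#' [generate_proteome_families()]) to plant family structure.
#'
#' @param n_phage,n_contaminant genome counts (>= 0).
#' @param seed integer seed; identical seeds give identical output.
#' @param config a [jumbo_config()] list.
#' @param alt_codes integer vector of alternative codes (15/90/91) planted into
#'   the first phages.
#' @param n_crass number of phages carrying the packaged synthetic crAss
#'   markers in frame.
#' @param crass_markers optional [Biostrings::AAStringSet] of marker proteins;
#'   defaults to the packaged synthetic markers.
#' @param phage_proteomes optional named list (length `n_phage`) of protein
#'   character vectors used as the phage gene proteins.
#' @param n_genes genes annotated per genome.
#' @return A list: `genomes` (DNAStringSet with `sample_id`, `country` in
#'   mcols), `annotations`, `host_predictions`, and `truth` (per-genome labels
#'   and `host_evidence_edges`).
#' @export
generate_community <- function(n_phage, n_contaminant, seed = 1L,
                               config = jumbo_config(),
                               alt_codes = integer(0), n_crass = 0L,
                               crass_markers = NULL,
                               phage_proteomes = NULL, n_genes = 30L) {
  stopifnot(n_phage >= 0, n_contaminant >= 0)
  if (length(alt_codes) + n_crass > n_phage) stop("more planted specials than phages")
  set.seed(seed)
  n_tot <- n_phage + n_contaminant
  if (n_tot == 0L) {
    return(list(genomes = DNAStringSet(), annotations = empty_annotation(),
                host_predictions = host_predictions(character(0), character(0),
                                                    character(0)),
                truth = list(labels = data.frame(), host_evidence_edges = NULL)))
  }
  ids <- c(if (n_phage) sprintf("phage_%02d", seq_len(n_phage)),
           if (n_contaminant) sprintf("contam_%02d", seq_len(n_contaminant)))
  is_phage <- c(rep(TRUE, n_phage), rep(FALSE, n_contaminant))
  countries <- c("China", "Ghana", "Denmark", "France", "Ireland", "Canada",
                 "US", "Australia")
  seqs <- character(n_tot)
  planted_code <- rep(11L, n_tot)
  is_crass <- rep(FALSE, n_tot)
  k <- 0L
  for (i in seq_len(n_tot)) {
    L <- sample(201000:300000, 1)
    if (is_phage[i] && k < length(alt_codes)) {
      k <- k + 1L
      rg <- generate_recoded_genome(alt_codes[k], L, seed = seed + i,
                                    config = config,
                                    self_validate = config$synth_self_validate)
      seqs[i] <- as.character(rg$genome[[1]])
      planted_code[i] <- alt_codes[k]
    } else {
      ## gene-structured (coding-dense) background under the standard code:
      ## real phage/bacterial contigs are coding-dense, and pure random
      ## sequence sits near the alternative-code density margin
      rg <- generate_recoded_genome(11L, L, seed = seed + i, config = config,
                                    self_validate = FALSE)
      seqs[i] <- as.character(rg$genome[[1]])
    }
  }
  genomes <- DNAStringSet(seqs)
  names(genomes) <- ids
  S4Vectors::mcols(genomes)$sample_id <- sprintf("S%03d", seq_len(n_tot))
  S4Vectors::mcols(genomes)$country <- sample(countries, n_tot, replace = TRUE)
  genomes <- plant_cursor(genomes)
  ## crAss markers planted in frame right after the recoded phages
  if (n_crass > 0L) {
    if (is.null(crass_markers)) crass_markers <- load_crass_markers()
    for (m in seq_len(n_crass)) {
      tgt <- ids[length(alt_codes) + m]
      for (mk in seq_along(crass_markers)) {
        genomes <- write_at_cursor(genomes, tgt,
                                   reverse_translate(as.character(crass_markers[[mk]])))
      }
      is_crass[match(tgt, ids)] <- TRUE
    }
  }
  ## gene annotations
  ann <- list()
  family_planted <- rep(NA_character_, n_tot)
  for (i in seq_len(n_tot)) {
    L <- Biostrings::width(genomes)[i]
    proteins <- if (is_phage[i] && !is.null(phage_proteomes)) {
      as.character(phage_proteomes[[i]])
    } else {
      vapply(seq_len(n_genes), function(x) random_protein(sample(100:400, 1)), "")
    }
    ng <- length(proteins)
    bounds <- sort(sample(seq(100L, floor(0.6 * L)), ng + 1L))
    starts <- bounds[-(ng + 1L)]
    ends <- pmin(starts + nchar(proteins) * 3L + 2L, bounds[-1L] - 1L)
    strand <- sample(c("+", "-"), ng, replace = TRUE, prob = c(0.7, 0.3))
    products <- rep("hypothetical protein", ng)
    hit_labels <- rep("none", ng)
    busco <- rep(FALSE, ng)
    if (is_phage[i]) {
      kw_genes <- seq_len(min(5L, ng))
      kw_products <- c("major capsid protein", "terminase large subunit",
                       "portal protein", "tail fiber protein",
                       "baseplate wedge subunit")
      products[kw_genes] <- kw_products[seq_along(kw_genes)]
      hit_labels[sample(ng, max(1L, round(0.3 * ng)))] <- "viral_family"
    } else {
      busco[sample(ng, max(ceiling(0.067 * ng) + 2L, round(0.3 * ng)))] <- TRUE
      hit_labels[sample(ng, round(0.4 * ng))] <- "microbial_family"
      products[sample(ng, 2L)] <- c("30S ribosomal protein S4",
                                    "DNA gyrase subunit A")
    }
    ann[[i]] <- data.frame(genome_id = ids[i], gene_index = seq_len(ng),
                           start = starts, end = ends, strand = strand,
                           protein = proteins, product_text = products,
                           hit_labels = hit_labels, busco_hit = busco,
                           stringsAsFactors = FALSE)
  }
  annotations <- do.call(rbind, ann)
  ## host-evidence spacers: contaminant arrays targeting phages, round-robin
  host_edges <- NULL
  if (n_phage > 0L && n_contaminant > 0L) {
    src <- ids[n_phage + 1L + (seq_len(n_phage) - 1L) %% n_contaminant]
    spec <- data.frame(source = src, target = ids[seq_len(n_phage)],
                       n_spacers = 1L, mismatches = 0L,
                       stringsAsFactors = FALSE)
    ## one array per contaminant covering all its targets
    planted <- plant_crispr_targeting(genomes, spec, seed = seed + 7777L,
                                      config = config, merge_by_source = TRUE)
    genomes <- planted$genomes
    host_edges <- planted$truth$spacer_edges
  }
  ## host predictions: contaminants stand in for host taxa; phages get 1-2
  phyla <- c("Bacillota_A", "Bacteroidota", "Pseudomonadota", "Spirochaetota")
  hp <- list()
  for (i in seq_len(n_phage)) {
    n_h <- sample(1:2, 1)
    ph <- sample(phyla, n_h)
    dom <- rep("Bacteria", n_h)
    if (i == n_phage && n_phage >= 4L) { ph <- "Methanobacteriota"; dom <- "Archaea"; n_h <- 1L }
    hp[[i]] <- host_predictions(rep(ids[i], n_h), dom[seq_len(n_h)], ph[seq_len(n_h)])
  }
  host_preds <- if (length(hp)) do.call(rbind, hp) else
    host_predictions(character(0), character(0), character(0))
  labels <- data.frame(genome_id = ids, is_phage = is_phage,
                       is_jumbo = is_phage,  # all generated phages are > 200 kb
                       busco_ratio_planted = vapply(ann, function(a) mean(a$busco_hit), 0),
                       genetic_code_planted = planted_code,
                       is_crass = is_crass,
                       family_planted = family_planted,
                       stringsAsFactors = FALSE)
  truth <- list(labels = labels, host_evidence_edges = host_edges)
  if (isTRUE(config$synth_self_validate)) {
    validate_community(genomes, annotations, truth, config)
  }
  list(genomes = genomes, annotations = annotations,
       host_predictions = host_preds, truth = truth)
}

## generation-time self-check: planted labels are re-detectable by the rules
validate_community <- function(genomes, annotations, truth, config) {
  for (i in seq_len(nrow(truth$labels))) {
    g <- truth$labels$genome_id[i]
    ann <- annotations[annotations$genome_id == g, , drop = FALSE]
    kw <- tolower(config$virus_keywords)
    nkw <- sum(vapply(tolower(ann$product_text),
                      function(p) any(vapply(kw, grepl, TRUE, x = p, fixed = TRUE)),
                      TRUE))
    bus <- mean(ann$busco_hit)
    if (truth$labels$is_phage[i]) {
      stopifnot(nkw >= config$min_keyword_genes, bus < config$busco_max_ratio)
    } else {
      stopifnot(bus >= config$busco_max_ratio)
    }
  }
  invisible(TRUE)
}

#' Generate a genome with a planted (possibly alternative) genetic code
#'
#' The genome is a dense series of genes (start codon, body codons, terminator)
#' separated by short random gaps. For an alternative code the reassigned stop
#' codon is seeded into gene bodies roughly every 15 codons, so standard-code
#' ORFs fragment below the 90-nt minimum while the planted code reads each gene
#' as one long ORF. At generation time the coding densities of all four codes
#' are recomputed with [find_orfs()] and the planted margin is verified.
#'
#' @param code 11, 15, 90 or 91.
#' @param length_bp genome length (>= 50 kb recommended; tiny lengths cannot
#'   achieve the margin and raise an error).
#' @param seed integer seed.
#' @param config a [jumbo_config()] list.
#' @param self_validate verify the planted density margin (default TRUE).
#' @return A list `genome` (DNAStringSet of 1), `code`, `densities` (when
#'   validated).
#' @export
generate_recoded_genome <- function(code, length_bp, seed = 1L,
                                    config = jumbo_config(),
                                    self_validate = TRUE) {
  code <- as.integer(code)
  if (!code %in% GENETIC_CODES) stop("unknown genetic code: ", code)
  if (length_bp < 3000L) {
    stop("length_bp too small to plant a code signal; use a larger length")
  }
  set.seed(seed)
  reassigned <- switch(as.character(code), "15" = "TAG", "90" = "TAA",
                       "91" = "TGA", "11" = NA_character_)
  all_codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                  c("A","C","G","T")), 1, paste, collapse = "")
  body_pool <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  stops_here <- orf_stop_codons(code)
  parts <- character(0)
  total <- 0L
  while (total < length_bp - 3000L) {
    n_codon <- sample(300:800, 1)
    body <- sample(body_pool, n_codon, replace = TRUE)
    if (!is.na(reassigned)) {
      hit <- which(runif(n_codon) < 1 / 15)
      body[hit] <- reassigned
    }
    gene <- paste0("ATG", paste(body, collapse = ""), sample(stops_here, 1))
    gap <- random_dna(sample(20:50, 1))
    parts <- c(parts, gene, gap)
    total <- total + nchar(gene) + nchar(gap)
  }
  seq <- paste(parts, collapse = "")
  seq <- paste0(seq, random_dna(length_bp - nchar(seq)))
  genome <- DNAStringSet(seq)
  names(genome) <- sprintf("recoded_%d", code)
  out <- list(genome = genome, code = code)
  if (self_validate) {
    dens <- vapply(GENETIC_CODES, function(cd) {
      find_orfs(genome[[1]], cd, config)$coded_fraction
    }, numeric(1))
    names(dens) <- as.character(GENETIC_CODES)
    gains <- dens[as.character(setdiff(GENETIC_CODES, 11L))] / dens[["11"]]
    if (code == 11L) {
      if (any(gains >= config$code_density_margin)) {
        stop("standard-code genome accidentally gained >= margin; regenerate")
      }
    } else if (dens[[as.character(code)]] < config$code_density_margin * dens[["11"]]) {
      stop("planted code margin not reached at this length; use a larger length_bp")
    }
    out$densities <- dens
  }
  out
}

#' Plant CRISPR arrays whose spacers target other genomes
#'
#' For each directed edge (source, target, n_spacers, mismatches) the source
#' genome gains a repeat-spacer array (random exact repeat of 36 nt, >= 3
#' copies) whose spacers are 32-nt substrings of the target genome carrying
#' exactly the requested number of substitutions, placed away from the spacer
#' ends so the coverage-clipping rule cannot cancel them. Spacer sets are
#' re-drawn when their flanking characters could blur the repeat boundary.
#'
#' @param genomes named [Biostrings::DNAStringSet].
#' @param edge_spec data.frame `source, target, n_spacers, mismatches`.
#' @param seed integer seed.
#' @param config a [jumbo_config()] list.
#' @param merge_by_source plant one array per source covering all its edges
#'   (needs >= 2 spacers per array; a lone edge gets a decoy self-consistent
#'   extra spacer drawn from the target).
#' @return `list(genomes, truth)` where `truth$spacer_edges` records source,
#'   target, spacer sequence, protospacer position and planted mismatches.
#' @export
plant_crispr_targeting <- function(genomes, edge_spec, seed = 1L,
                                   config = jumbo_config(),
                                   merge_by_source = FALSE) {
  if (nrow(edge_spec) == 0L) {
    return(list(genomes = genomes,
                truth = list(spacer_edges = NULL)))
  }
  stopifnot(all(edge_spec$source %in% names(genomes)),
            all(edge_spec$target %in% names(genomes)))
  spacer_len <- 32L
  repeat_len <- 36L
  if (any(edge_spec$mismatches > spacer_len)) stop("mismatches exceed spacer length")
  set.seed(seed)
  genomes <- plant_cursor(genomes)
  edges <- list()
  groups <- if (merge_by_source) split(seq_len(nrow(edge_spec)), edge_spec$source)
            else as.list(seq_len(nrow(edge_spec)))
  for (grp in groups) {
    rows <- edge_spec[grp, , drop = FALSE]
    src <- rows$source[1]
    spacer_plan <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
      data.frame(target = rows$target[r],
                 mismatches = rep(rows$mismatches[r], rows$n_spacers[r]),
                 decoy = FALSE, stringsAsFactors = FALSE)
    }))
    if (nrow(spacer_plan) < 2L) {  # arrays need >= 3 repeats, i.e. >= 2 spacers
      ## pad with a decoy spacer that matches no genome (random sequence)
      spacer_plan <- rbind(spacer_plan,
                           data.frame(target = spacer_plan$target[1],
                                      mismatches = 0L, decoy = TRUE,
                                      stringsAsFactors = FALSE))
    }
    for (attempt in 1:50) {
      R <- random_dna(repeat_len)
      draws <- lapply(seq_len(nrow(spacer_plan)), function(r) {
        if (spacer_plan$decoy[r]) {
          list(spacer = random_dna(spacer_len), start = NA_integer_)
        } else {
          draw_protospacer(genomes, spacer_plan$target[r], spacer_len,
                           spacer_plan$mismatches[r], config)
        }
      })
      spacers <- vapply(draws, `[[`, "", "spacer")
      firsts <- substr(spacers, 1, 1)
      lasts <- substr(spacers, spacer_len, spacer_len)
      ## avoid boundary blur: spacers must not all share a first or last base
      if (length(unique(firsts)) > 1 && length(unique(lasts)) > 1) break
      if (attempt == 50) stop("could not plant a boundary-safe array")
    }
    array_seq <- paste0(R, paste(vapply(spacers, function(s) paste0(s, R), ""),
                                 collapse = ""))
    ## flank guards: distinct from spacer boundary characters
    array_seq <- paste0(guard_base(lasts), array_seq, guard_base(firsts))
    genomes <- write_at_cursor(genomes, src, array_seq)
    for (r in seq_len(nrow(spacer_plan))) {
      if (spacer_plan$decoy[r]) next
      edges[[length(edges) + 1L]] <- data.frame(
        source = src, target = spacer_plan$target[r],
        spacer = spacers[r],
        protospacer_start = draws[[r]]$start,
        mismatches = spacer_plan$mismatches[r],
        stringsAsFactors = FALSE)
    }
  }
  truth <- list(spacer_edges = do.call(rbind, edges))
  list(genomes = genomes, truth = truth)
}

## a base different from every character in v (breaks flank agreement)
guard_base <- function(v) {
  setdiff(c("A", "C", "G", "T"), v)[1]
}

## read a protospacer from the target's gene zone and apply interior mismatches
draw_protospacer <- function(genomes, target, spacer_len, mismatches, config) {
  L <- Biostrings::width(genomes)[names(genomes) == target]
  lo <- floor(0.30 * L); hi <- floor(0.60 * L) - spacer_len
  pos <- sample(lo:hi, 1)
  proto <- as.character(subseq(genomes[[which(names(genomes) == target)]],
                               pos, pos + spacer_len - 1L))
  spacer <- proto
  if (mismatches > 0L) {
    margin <- spacer_len - ceiling(config$spacer_min_coverage * spacer_len)
    interior <- (margin + 1L):(spacer_len - margin)
    sites <- sample(interior, mismatches)
    v <- strsplit(spacer, "")[[1]]
    for (s in sites) v[s] <- sample(setdiff(c("A","C","G","T"), v[s]), 1)
    spacer <- paste(v, collapse = "")
  }
  list(spacer = spacer, start = pos)
}

#' Generate proteomes with planted family structure
#'
#' Genomes within a family share `within` of their proteins (near-identical
#' copies, ~98% identity); genomes in different families share `between`
#' (copies from a global pool). Remaining proteins are unique random sequences.
#'
#' @param n_per_family integer vector of genomes per family.
#' @param within,between target sharing fractions (within must exceed between).
#' @param proteome_size proteins per genome.
#' @param seed integer seed.
#' @return A list: `proteomes` (named list of character vectors), `truth`
#'   (data.frame `genome_id`, `family_planted`).
#' @export
generate_proteome_families <- function(n_per_family, within = 0.6, between = 0,
                                       proteome_size = 25L, seed = 1L) {
  if (within <= between) stop("within-family sharing must exceed between-family sharing")
  set.seed(seed)
  n_between <- round(between * proteome_size)
  n_within <- round(within * proteome_size) - n_between
  if (n_within < 0) stop("incompatible sharing fractions")
  global_pool <- vapply(seq_len(max(n_between, 1L)), function(x)
    random_protein(sample(100:400, 1)), "")[seq_len(n_between)]
  proteomes <- list()
  fam_label <- character(0)
  for (f in seq_along(n_per_family)) {
    core <- vapply(seq_len(max(n_within, 1L)), function(x)
      random_protein(sample(100:400, 1)), "")[seq_len(n_within)]
    for (g in seq_len(n_per_family[f])) {
      gid <- sprintf("F%d_g%d", f, g)
      shared <- vapply(c(global_pool, core), mutate_protein, "", rate = 0.01)
      unique_n <- proteome_size - length(shared)
      uniq <- vapply(seq_len(max(unique_n, 1L)), function(x)
        random_protein(sample(100:400, 1)), "")[seq_len(unique_n)]
      proteomes[[gid]] <- unname(c(shared, uniq))
      fam_label <- c(fam_label, sprintf("family_%d", f))
    }
  }
  list(proteomes = proteomes,
       truth = data.frame(genome_id = names(proteomes),
                          family_planted = fam_label,
                          stringsAsFactors = FALSE))
}

#' Generate a compositional abundance matrix with planted correlations
#'
#' Latent per-taxon log-abundances are standard normal across samples; planted
#' pairs get log-scale correlation +/- 0.9. Exponentiated basis abundances are
#' closed to compositions per sample and scaled to multinomial counts at total
#' depth 1e5 (small resampling noise relative to the planted effects).
#'
#' @param n_taxa number of taxa (>= 3).
#' @param n_samples number of samples.
#' @param planted_pairs data.frame `i, j, sign` (1-based taxon indices,
#'   sign in `{"+", "-"}`); each taxon may appear in at most one pair.
#' @param seed integer seed.
#' @param depth total count per sample.
#' @return A list: `counts` (taxa x samples integer matrix), `latent` (the
#'   basis log-abundances), `truth` (the planted pairs with numeric signs).
#' @export
generate_abundance_matrix <- function(n_taxa, n_samples, planted_pairs = NULL,
                                      seed = 1L, depth = 1e5) {
  if (n_taxa < 3L) stop("correlation inference undefined below 3 taxa")
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(i = integer(), j = integer(),
                                sign = character(), stringsAsFactors = FALSE)
  }
  used <- c(planted_pairs$i, planted_pairs$j)
  if (anyDuplicated(used)) stop("each taxon may appear in at most one planted pair")
  if (length(used) && max(used) > n_taxa) stop("planted pair index out of range")
  set.seed(seed)
  Z <- matrix(rnorm(n_taxa * n_samples), n_taxa, n_samples)
  rho <- 0.9
  for (r in seq_len(nrow(planted_pairs))) {
    i <- planted_pairs$i[r]; j <- planted_pairs$j[r]
    s <- if (planted_pairs$sign[r] %in% c("+", "positive", "1")) 1 else -1
    Z[j, ] <- s * (rho * Z[i, ] + sqrt(1 - rho^2) * Z[j, ])
  }
  basis <- exp(Z)
  frac <- sweep(basis, 2, colSums(basis), "/")
  counts <- vapply(seq_len(n_samples), function(s) {
    as.integer(rmultinom(1, size = depth, prob = frac[, s]))
  }, integer(n_taxa))
  rownames(counts) <- sprintf("taxon_%02d", seq_len(n_taxa))
  rownames(Z) <- rownames(counts)
  truth <- planted_pairs
  truth$sign_num <- ifelse(truth$sign %in% c("+", "positive", "1"), 1, -1)
  list(counts = counts, latent = Z, truth = truth)
}

## fixed codon per amino acid for in-frame marker planting
reverse_translate <- function(protein) {
  table <- c(A="GCT", R="CGT", N="AAT", D="GAT", C="TGT", Q="CAA", E="GAA",
             G="GGT", H="CAT", I="ATT", L="CTT", K="AAA", M="ATG", F="TTT",
             P="CCT", S="TCT", T="ACT", W="TGG", Y="TAT", V="GTT")
  aa <- strsplit(protein, "")[[1]]
  if (!all(aa %in% names(table))) stop("cannot reverse-translate: unknown residue")
  paste0("ATG", paste(table[aa], collapse = ""), "TAA")
}

#' Load the packaged synthetic crAss marker proteins
#'
#' Synthetic stand-ins (random sequences) for the crAssphage polymerase and
#' terminase markers, used to exercise the translated-homology classifier; real
#' analyses should substitute the genuine marker sequences.
#'
#' @return An [Biostrings::AAStringSet] named `polymerase`, `terminase`.
#' @export
load_crass_markers <- function() {
  path <- system.file("extdata", "crass_markers_synthetic.faa",
                      package = "jumbophage")
  if (!nzchar(path)) stop("packaged marker FASTA not found")
  mk <- Biostrings::readAAStringSet(path)
  names(mk) <- sub("\\s.*$", "", names(mk))
  mk
}
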