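#' Pipeline configuration with published default thresholds
#'
#' Collects every tunable threshold used across the pipeline in one list, so
#' that no stage carries hidden constants. Defaults are the values used
#' throughout the jumbo-phage literature for each rule: the >200 kb jumbo size
#' cut, the 2-keyword / exclusion-term / spacer-evidence phage rule, the
#' 0.067 BUSCO-ratio retention bound, the 0.5/0.9 lysogeny-score cuts, the 10%
#' coding-density gain for alternative genetic codes, the crAss-like homology
#' gates (70 kb, E < 1e-10, 95% identity over 80% of the genome), the CRISPR
#' spacer match rule (<= 1 mismatch, >= 95% coverage), the dual family
#' demarcation thresholds (patristic distance >= 0.05, shared orthologue
#' fraction < 10%), and the abundance zeroing/correlation settings (breadth
#' <= 0.25 zeroed, 1,000 bootstrap iterations, p < 0.001).
#'
#' @param ... named overrides for any default listed below.
#' @return A named list of class `jumbo_config`.
#' @export
jumbo_config <- function(...) {
  cfg <- list(
    ## discovery -------------------------------------------------------------
    jumbo_min_bp        = 200000L,  # is_jumbo iff length > this (strict)
    min_keyword_genes   = 2L,
    virus_keywords      = c("capsid", "phage", "terminase", "base plate",
                            "baseplate", "prohead", "virion", "virus", "viral",
                            "tape measure", "tapemeasure", "neck", "tail",
                            "head", "bacteriophage", "prophage", "portal",
                            "DNA packaging", "T4", "p22", "holin"),
    exclusion_terms     = c("ribosomal protein", "preprotein translocase",
                            "DNA gyrase subunit A"),
    busco_max_ratio     = 0.067,    # retained iff ratio < this (strict)
    viral_family_min    = 0.10,     # fraction of genes with viral_family hits
    microbial_family_max = 0.02,    # fraction of genes with microbial_family hits
    strand_run_min      = 10L,      # consecutive same-strand genes
    nt_signature_fun    = NULL,     # pluggable predicate(genome) -> logical
    ## lifestyle --------------------------------------------------------------
    lifestyle_virulent_max = 0.5,   # virulent iff score < 0.5
    lifestyle_temperate_min = 0.9,  # temperate iff score > 0.9
    ## genetic codes ----------------------------------------------------------
    code_density_margin = 1.10,     # alt code assigned iff density >= 1.10 x code 11
    orf_min_nt          = 90L,
    orf_start_codons    = c("ATG", "GTG", "TTG"),
    ## crAss-like -------------------------------------------------------------
    crass_min_bp        = 70000L,   # genomes exceeding 70 kb are eligible
    crass_max_evalue    = 1e-10,
    crass_min_identity  = 0.95,
    crass_min_aligned   = 0.80,
    crass_fragment_nt   = 1000L,
    ## protein alignment / Karlin-Altschul ------------------------------------
    ka_lambda           = 0.318,    # ungapped BLOSUM62
    ka_k                = 0.13,
    aa_seed_word        = 5L,       # exact-word seed length for seeded searches
    gap_opening         = 10,
    gap_extension       = 1,
    ## CRISPR -----------------------------------------------------------------
    crispr_min_repeats  = 3L,
    crispr_repeat_range = c(23L, 47L),
    crispr_spacer_range = c(26L, 50L),
    crispr_search_window = 8L,
    spacer_max_mismatch = 1L,
    spacer_min_coverage = 0.95,
    ## taxonomy ---------------------------------------------------------------
    rbh_max_evalue      = 1e-5,
    rbh_min_identity    = 0.30,
    rbh_min_coverage    = 0.50,     # of the shorter protein
    family_min_distance = 0.05,     # patristic distance on the proteomic tree
    family_max_shared   = 0.10,     # shared orthologue fraction (strict <)
    ## abundance / correlation -------------------------------------------------
    breadth_zero_max    = 0.25,     # zeroed iff breadth <= 0.25
    sparcc_iterations   = 20L,
    sparcc_exclusion_threshold = 0.1,
    sparcc_exclusion_rounds = 10L,
    n_bootstrap         = 1000L,
    p_cutoff            = 0.001,
    pseudo_count_scale  = 100,      # mean depth -> integer pseudo-counts
    ## synthetic data ----------------------------------------------------------
    synth_self_validate = TRUE,
    seed                = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  class(cfg) <- c("jumbo_config", "list")
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$jumbo_min_bp > 0,
    cfg$min_keyword_genes >= 1,
    cfg$busco_max_ratio > 0, cfg$busco_max_ratio < 1,
    cfg$lifestyle_virulent_max <= cfg$lifestyle_temperate_min,
    cfg$code_density_margin >= 1,
    cfg$orf_min_nt >= 3,
    cfg$crass_max_evalue > 0,
    cfg$crass_min_identity > 0, cfg$crass_min_identity <= 1,
    cfg$crass_min_aligned > 0, cfg$crass_min_aligned <= 1,
    cfg$spacer_max_mismatch >= 0,
    cfg$spacer_min_coverage > 0, cfg$spacer_min_coverage <= 1,
    cfg$crispr_min_repeats >= 2,
    diff(cfg$crispr_repeat_range) >= 0,
    diff(cfg$crispr_spacer_range) >= 0,
    cfg$rbh_max_evalue > 0,
    cfg$rbh_min_identity >= 0, cfg$rbh_min_identity <= 1,
    cfg$family_min_distance >= 0,
    cfg$family_max_shared >= 0, cfg$family_max_shared <= 1,
    cfg$breadth_zero_max >= 0, cfg$breadth_zero_max <= 1,
    cfg$sparcc_iterations >= 1,
    cfg$n_bootstrap >= 1,
    cfg$p_cutoff > 0, cfg$p_cutoff < 1
  )
  invisible(cfg)
}

#' Read a key=value configuration file
#'
#' Lines of the form `key = value` (comments with `#`) override the defaults of
#' [jumbo_config()]. Values are parsed as numeric when possible, `TRUE`/`FALSE`
#' as logical, and comma-separated lists as character vectors.
#'
#' @param path path to the configuration file.
#' @return A `jumbo_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (grepl(",", val, fixed = TRUE)) {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    } else if (val %in% c("TRUE", "FALSE", "true", "false")) {
      val <- as.logical(toupper(val))
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      val <- as.numeric(val)
    }
    over[[key]] <- val
  }
  do.call(jumbo_config, over)
}
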