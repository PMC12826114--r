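#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   DNAString AAString AAStringSet matchPattern reverseComplement translate
#'   subseq pairwiseAlignment
#' @importFrom IRanges IRanges reduce width
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom stats cov median rgamma rmultinom rnorm runif setNames var
#' @importFrom utils read.delim write.table head
NULL

## Genome collections are DNAStringSet objects: names are genome_ids, optional
## per-genome metadata (sample_id, country) lives in S4Vectors::mcols().
## Gene annotations are plain data.frames (one row per gene). Coverage tracks
## are lists of (genome_id, sample_id, depth-vector).

#' Read genome sequences from FASTA
#'
#' Sequences are upper-cased and `U` is mapped to `T`. Header text after the
#' first whitespace is dropped from the genome id.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by genome id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ## readBStringSet first so we can normalise case/U and give format errors
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e)))
  if (length(raw) == 0L) return(DNAStringSet())
  ids <- sub("\\s.*$", "", names(raw))
  seqs <- toupper(as.character(raw))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate genome id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write genome sequences to FASTA
#'
#' @param genomes a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_fasta <- function(genomes, path) {
  writeXStringSet(genomes, path, width = 80L)
  invisible(path)
}

annotation_columns <- c("genome_id", "gene_index", "start", "end", "strand",
                        "protein", "product_text", "hit_labels", "busco_hit")

#' Read a per-gene annotation table
#'
#' Tab-separated with header columns `genome_id, gene_index, start, end,
#' strand, protein, product_text, hit_labels, busco_hit`. Coordinates are
#' 1-based inclusive. `hit_labels` is a comma-separated subset of
#' `viral_family`, `microbial_family`, `none`.
#'
#' @param path path to the TSV file.
#' @return A data.frame of gene annotations (possibly 0-row).
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE)
  missing <- setdiff(annotation_columns, names(df))
  if (length(missing)) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) return(empty_annotation())
  ann <- data.frame(
    genome_id    = df$genome_id,
    gene_index   = as.integer(df$gene_index),
    start        = as.integer(df$start),
    end          = as.integer(df$end),
    strand       = df$strand,
    protein      = df$protein,
    product_text = df$product_text,
    hit_labels   = df$hit_labels,
    busco_hit    = tolower(df$busco_hit) %in% c("true", "t", "1"),
    stringsAsFactors = FALSE
  )
  validate_annotations(ann)
  ann
}

empty_annotation <- function() {
  data.frame(genome_id = character(), gene_index = integer(),
             start = integer(), end = integer(), strand = character(),
             protein = character(), product_text = character(),
             hit_labels = character(), busco_hit = logical(),
             stringsAsFactors = FALSE)
}

validate_annotations <- function(ann, genomes = NULL) {
  bad <- which(ann$end < ann$start)
  if (length(bad)) {
    stop("annotation end < start for gene(s): ",
         paste(ann$genome_id[bad], ann$gene_index[bad], sep = ":", collapse = ", "))
  }
  if (any(ann$start < 1L)) stop("annotation start below 1")
  if (!all(ann$strand %in% c("+", "-"))) {
    stop("unknown strand symbol(s): ",
         paste(unique(setdiff(ann$strand, c("+", "-"))), collapse = ", "))
  }
  dup <- duplicated(paste(ann$genome_id, ann$gene_index))
  if (any(dup)) stop("duplicate gene_index within genome")
  if (!is.null(genomes)) {
    len <- setNames(Biostrings::width(genomes), names(genomes))
    known <- ann$genome_id %in% names(len)
    over <- known & ann$end > len[ann$genome_id]
    if (any(over)) stop("annotation extends beyond genome length")
  }
  invisible(ann)
}

#' Write a per-gene annotation table
#' @param ann annotation data.frame.
#' @param path output path.
#' @export
write_annotation_table <- function(ann, path) {
  out <- ann[, annotation_columns]
  out$busco_hit <- ifelse(out$busco_hit, "true", "false")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-base or interval coverage table
#'
#' Two dialects are accepted and auto-detected from the header:
#' \describe{
#'   \item{per-base}{columns `genome_id, sample_id, position, depth`, with
#'     1-based positions; unlisted positions are depth 0.}
#'   \item{interval}{columns `genome_id, sample_id, start, end, depth`, with
#'     0-based half-open intervals (the `bedtools genomecov -bga` convention):
#'     a row with start 0 and end 5 covers 1-based positions 1 through 5.}
#' }
#'
#' @param path path to the TSV file.
#' @param genome_lengths named integer vector of genome lengths used to
#'   densify the depth vectors.
#' @return A list of coverage tracks, each `list(genome_id, sample_id, depth)`.
#' @export
read_coverage_table <- function(path, genome_lengths) {
  if (!file.exists(path)) stop("coverage table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (all(c("genome_id", "sample_id", "position", "depth") %in% names(df))) {
    dialect <- "position"
  } else if (all(c("genome_id", "sample_id", "start", "end", "depth") %in% names(df))) {
    dialect <- "interval"
  } else {
    stop("unrecognised coverage table header in ", path)
  }
  unknown <- setdiff(unique(df$genome_id), names(genome_lengths))
  if (length(unknown)) stop("coverage rows for unknown genome(s): ",
                            paste(unknown, collapse = ", "))
  keys <- unique(df[, c("genome_id", "sample_id")])
  tracks <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    g <- keys$genome_id[i]; s <- keys$sample_id[i]
    L <- genome_lengths[[g]]
    depth <- numeric(L)
    rows <- df[df$genome_id == g & df$sample_id == s, , drop = FALSE]
    if (dialect == "position") {
      if (any(rows$position < 1L | rows$position > L)) {
        stop("coverage position outside genome ", g)
      }
      depth[rows$position] <- depth[rows$position] + rows$depth
    } else {
      if (any(rows$start < 0L | rows$end > L | rows$end < rows$start)) {
        stop("coverage interval outside genome ", g)
      }
      for (r in seq_len(nrow(rows))) {
        if (rows$end[r] > rows$start[r]) {
          idx <- (rows$start[r] + 1L):rows$end[r]  # 0-based half-open -> 1-based
          depth[idx] <- depth[idx] + rows$depth[r]
        }
      }
    }
    if (any(depth < 0)) stop("negative depth for genome ", g)
    tracks[[i]] <- coverage_track(g, s, depth)
  }
  ## genomes with no rows at all get all-zero tracks for every listed sample
  samples <- unique(df$sample_id)
  missing_g <- setdiff(names(genome_lengths), unique(df$genome_id))
  for (g in missing_g) {
    for (s in samples) {
      tracks[[length(tracks) + 1L]] <-
        coverage_track(g, s, numeric(genome_lengths[[g]]))
    }
  }
  tracks
}

#' Construct a coverage track
#' @param genome_id,sample_id identifiers.
#' @param depth numeric depth vector, one entry per genome position.
#' @return A `coverage_track` list.
#' @export
coverage_track <- function(genome_id, sample_id, depth) {
  stopifnot(is.numeric(depth), all(depth >= 0))
  structure(list(genome_id = genome_id, sample_id = sample_id, depth = depth),
            class = "coverage_track")
}

#' Write coverage tracks in the per-base dialect (non-zero positions only)
#' @param tracks list of coverage tracks.
#' @param path output path.
#' @export
write_coverage_table <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    nz <- which(tr$depth > 0)
    if (!length(nz)) return(NULL)
    data.frame(genome_id = tr$genome_id, sample_id = tr$sample_id,
               position = nz, depth = tr$depth[nz], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(empty_cov_df())))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

empty_cov_df <- function() {
  data.frame(genome_id = character(), sample_id = character(),
             position = integer(), depth = numeric(), stringsAsFactors = FALSE)
}

#' Read a host-prediction table
#'
#' Tab-separated with columns `genome_id, host_lineage` (semicolon-separated
#' taxa, domain first) and optional `confidence`.
#'
#' @param path path to the TSV file.
#' @return A data.frame with columns `genome_id`, `host_lineage` (list column),
#'   `host_domain`, `host_phylum`, `confidence`.
#' @export
read_host_table <- function(path) {
  if (!file.exists(path)) stop("host table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE)
  if (!all(c("genome_id", "host_lineage") %in% names(df))) {
    stop("host table needs columns genome_id and host_lineage")
  }
  lineages <- strsplit(df$host_lineage, ";", fixed = TRUE)
  lineages <- lapply(lineages, trimws)
  if (any(vapply(lineages, length, 1L) == 0L)) stop("empty host lineage")
  domains <- vapply(lineages, `[`, "", 1L)
  if (!all(domains %in% c("Bacteria", "Archaea"))) {
    stop("host domain must be Bacteria or Archaea")
  }
  host_predictions(
    genome_id = df$genome_id,
    host_domain = domains,
    host_phylum = vapply(lineages, function(x) if (length(x) >= 2) x[2] else NA_character_, ""),
    host_lineage = df$host_lineage,
    confidence = if ("confidence" %in% names(df)) as.numeric(df$confidence) else NA_real_
  )
}

#' Construct a host-prediction table
#' @param genome_id,host_domain,host_phylum,host_lineage,confidence columns.
#' @return A data.frame of host predictions.
#' @export
host_predictions <- function(genome_id, host_domain, host_phylum,
                             host_lineage = paste(host_domain, host_phylum, sep = ";"),
                             confidence = NA_real_) {
  data.frame(genome_id = genome_id, host_domain = host_domain,
             host_phylum = host_phylum, host_lineage = host_lineage,
             confidence = rep(confidence, length.out = length(genome_id)),
             stringsAsFactors = FALSE)
}

#' Read a lifestyle-score table
#'
#' Tab-separated with columns `genome_id, score, provirus_flag`.
#'
#' @param path path to the TSV file.
#' @return A data.frame with typed columns.
#' @export
read_lifestyle_table <- function(path) {
  if (!file.exists(path)) stop("lifestyle table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!all(c("genome_id", "score", "provirus_flag") %in% names(df))) {
    stop("lifestyle table needs columns genome_id, score, provirus_flag")
  }
  data.frame(genome_id = as.character(df$genome_id),
             score = as.numeric(df$score),
             provirus_flag = tolower(as.character(df$provirus_flag)) %in%
               c("true", "t", "1"),
             stringsAsFactors = FALSE)
}

## split a comma-separated hit_labels field into a character set
parse_hit_labels <- function(x) {
  out <- strsplit(x, ",", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}
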