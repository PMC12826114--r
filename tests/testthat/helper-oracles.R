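## Independent brute-force oracles used to cross-check the package
## implementations. These deliberately share no code with the package: plain
## character loops and closed forms.

rc_chars <- function(v) rev(chartr("ACGT", "TGCA", v))

## Sliding-window Hamming scan implementing the spacer-match rule directly:
## full-length placements, up to `margin` terminal positions clipped, <= max_mm
## substitutions in the kept window, N always a mismatch. Returns one row per
## locus with the best (max coverage, min mismatch) call.
oracle_spacer_scan <- function(spacer, genome_seq, min_coverage = 0.95,
                               max_mm = 1L) {
  sp <- strsplit(spacer, "")[[1]]
  L <- length(sp)
  margin <- L - ceiling(min_coverage * L)
  g <- strsplit(genome_seq, "")[[1]]
  n <- length(g)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") sp else rc_chars(sp)
    for (pos in seq_len(n - L + 1L)) {
      win <- g[pos:(pos + L - 1L)]
      mmv <- win != pat | win == "N" | pat == "N"
      found <- NULL
      for (clip in 0:margin) {
        for (a in 0:clip) {
          b <- clip - a
          mm <- sum(mmv[(a + 1L):(L - b)])
          if (mm <= max_mm) {
            cand <- list(mm = mm, cov = (L - clip) / L)
            if (is.null(found) || cand$cov > found$cov ||
                (cand$cov == found$cov && cand$mm < found$mm)) found <- cand
          }
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) {
        hits[[length(hits) + 1L]] <- data.frame(
          target_start = pos, strand = strand,
          mismatches = found$mm, coverage = found$cov)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(target_start = integer(), strand = character(),
                      mismatches = integer(), coverage = numeric()))
  }
  df <- do.call(rbind, hits)
  ## collapse overlapping placements exactly like the rule demands
  df <- df[order(-df$coverage, df$mismatches, df$target_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    ov <- abs(df$target_start - df$target_start[i]) < L & seq_len(nrow(df)) > i
    keep[ov] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$target_start), , drop = FALSE]
}

## TRUE when no lag d in [49, 97] carries an equality run >= 23 nt anywhere,
## i.e. the sequence cannot contain any qualifying CRISPR repeat pair.
oracle_no_repeat_structure <- function(genome_seq) {
  g <- strsplit(genome_seq, "")[[1]]
  n <- length(g)
  for (d in 49:97) {
    eq <- g[seq_len(n - d)] == g[(d + 1):n]
    r <- rle(eq)
    if (any(r$values & r$lengths >= 23)) return(FALSE)
  }
  TRUE
}

## closed-form SparCC basis variances and correlations for exactly 3 taxa
oracle_sparcc3 <- function(frac) {
  lf <- log(frac)
  t12 <- stats::var(lf[1, ] - lf[2, ])
  t13 <- stats::var(lf[1, ] - lf[3, ])
  t23 <- stats::var(lf[2, ] - lf[3, ])
  w <- c((t12 + t13 - t23) / 2, (t12 + t23 - t13) / 2, (t13 + t23 - t12) / 2)
  Tm <- matrix(c(0, t12, t13, t12, 0, t23, t13, t23, 0), 3)
  rho <- matrix(1, 3, 3)
  for (i in 1:2) for (j in (i + 1):3) {
    rho[i, j] <- rho[j, i] <-
      max(min((w[i] + w[j] - Tm[i, j]) / (2 * sqrt(w[i] * w[j])), 1), -1)
  }
  list(omega = w, rho = rho)
}

## the package's Dirichlet resampling, replayed for oracle comparison
replay_dirichlet <- function(counts, seed) {
  set.seed(seed)
  g <- matrix(stats::rgamma(length(counts), shape = counts + 1, rate = 1),
              nrow(counts))
  sweep(g, 2, colSums(g), "/")
}

## random additive distance matrix: patristic distances of a random tree
oracle_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(n) stats::runif(n, 0.1, 1))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  stats::cophenetic(tr)
}

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
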