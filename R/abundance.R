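#' Mean depth, breadth, and the zeroing rule for one coverage track
#'
#' Breadth is the fraction of genome positions with depth >= 1. The reported
#' abundance is zeroed when reads provide < 1x coverage across >= 75% of the
#' genome, i.e. when breadth <= 0.25 (boundary inclusive).
#'
#' @param track a coverage track (see [coverage_track()]).
#' @param config a [jumbo_config()] list.
#' @return `list(mean_depth, breadth, zeroed, abundance)` where `abundance` is
#'   0 when zeroed and the mean depth otherwise.
#' @export
compute_abundance <- function(track, config = jumbo_config()) {
  depth <- track$depth
  if (length(depth) == 0L) stop("empty depth vector")
  mean_depth <- mean(depth)
  breadth <- mean(depth >= 1)
  zeroed <- breadth <= config$breadth_zero_max
  list(mean_depth = mean_depth, breadth = breadth, zeroed = zeroed,
       abundance = if (zeroed) 0 else mean_depth)
}

#' Genome x sample abundance matrix with the breadth-zeroing rule
#'
#' @param tracks list of coverage tracks.
#' @param config a [jumbo_config()] list.
#' @return A list with matrices `mean_depth`, `breadth`, `zeroed`, and
#'   `abundance` (zero-ruled mean depth), rows = genomes, cols = samples.
#' @export
abundance_matrix <- function(tracks, config = jumbo_config()) {
  gids <- unique(vapply(tracks, `[[`, "", "genome_id"))
  sids <- unique(vapply(tracks, `[[`, "", "sample_id"))
  dims <- list(gids, sids)
  md <- matrix(NA_real_, length(gids), length(sids), dimnames = dims)
  br <- matrix(NA_real_, length(gids), length(sids), dimnames = dims)
  ze <- matrix(NA, length(gids), length(sids), dimnames = dims)
  ab <- matrix(NA_real_, length(gids), length(sids), dimnames = dims)
  for (tr in tracks) {
    a <- compute_abundance(tr, config)
    md[tr$genome_id, tr$sample_id] <- a$mean_depth
    br[tr$genome_id, tr$sample_id] <- a$breadth
    ze[tr$genome_id, tr$sample_id] <- a$zeroed
    ab[tr$genome_id, tr$sample_id] <- a$abundance
  }
  list(mean_depth = md, breadth = br, zeroed = ze, abundance = ab)
}

## Dirichlet-posterior fractions: one draw per sample, alpha = counts + 1
dirichlet_fractions <- function(counts) {
  D <- nrow(counts); n <- ncol(counts)
  g <- matrix(rgamma(D * n, shape = counts + 1, rate = 1), D, n)
  sweep(g, 2, colSums(g), "/")
}

## log-ratio variance matrix t_ij = Var(log(x_i / x_j)) across samples
log_ratio_variances <- function(frac) {
  lf <- log(frac)
  C <- cov(t(lf))
  v <- diag(C)
  outer(v, v, "+") - 2 * C
}

## solve the basis variances from T given an exclusion mask, then correlations
basis_correlations <- function(T, excluded) {
  D <- nrow(T)
  inc <- !excluded
  diag(inc) <- FALSE
  M <- inc * 1
  diag(M) <- rowSums(inc)
  t_i <- rowSums(T * inc)
  omega <- tryCatch(solve(M, t_i), error = function(e) rep(NA_real_, D))
  om <- pmax(omega, 1e-12)
  rho <- (outer(om, om, "+") - T) / (2 * sqrt(outer(om, om)))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  rho
}

## one SparCC estimation iteration on a fraction matrix, with pair exclusion
sparcc_once <- function(frac, config) {
  D <- nrow(frac)
  T <- log_ratio_variances(frac)
  excluded <- matrix(FALSE, D, D)
  rho <- basis_correlations(T, excluded)
  if (D >= 4) {
    for (round in seq_len(config$sparcc_exclusion_rounds)) {
      cand <- abs(rho)
      diag(cand) <- 0
      cand[excluded] <- 0
      m <- max(cand)
      if (m <= config$sparcc_exclusion_threshold) break
      idx <- which(cand == m, arr.ind = TRUE)[1, ]
      excluded[idx[1], idx[2]] <- excluded[idx[2], idx[1]] <- TRUE
      ## a taxon must keep at least 3 included partners to stay solvable
      if (any(rowSums(!excluded) - 1 < 3)) {
        excluded[idx[1], idx[2]] <- excluded[idx[2], idx[1]] <- FALSE
        break
      }
      rho <- basis_correlations(T, excluded)
    }
  }
  rho
}

#' SparCC-style basis correlations from compositional counts
#'
#' Per estimation iteration, taxon fractions are resampled from a Dirichlet
#' posterior (counts + 1) per sample; log-ratio variances
#' `t_ij = Var(log(x_i/x_j))` are converted to basis variances by solving the
#' SparCC linear system, giving correlations
#' `rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))` clamped to `[-1, 1]`.
#' The most-correlated pair above the exclusion threshold is iteratively
#' excluded and the system re-solved (up to 10 rounds; skipped below 4 taxa
#' where exclusion makes the system singular). The final estimate is the
#' entrywise median over estimation iterations.
#'
#' Taxa with identical counts in all samples have no resampling-free variance
#' signal; their correlations are reported `NA` and flagged.
#'
#' @param counts non-negative taxa x samples count matrix (>= 3 taxa and
#'   samples).
#' @param config a [jumbo_config()] list (`sparcc_iterations`,
#'   `sparcc_exclusion_threshold`, `sparcc_exclusion_rounds`).
#' @param seed integer seed for the Dirichlet resampling.
#' @return The correlation matrix with attribute `undefined_taxa` (integer
#'   indices of constant taxa, if any).
#' @export
sparcc_correlations <- function(counts, config = jumbo_config(),
                                seed = config$seed) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 3L || ncol(counts) < 3L) {
    stop("sparcc_correlations requires >= 3 taxa and >= 3 samples")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  constant <- which(apply(counts, 1, function(r) length(unique(r)) == 1L))
  set.seed(seed)
  D <- nrow(counts)
  rhos <- array(NA_real_, c(D, D, config$sparcc_iterations))
  for (it in seq_len(config$sparcc_iterations)) {
    frac <- dirichlet_fractions(counts)
    rhos[, , it] <- sparcc_once(frac, config)
  }
  rho <- apply(rhos, c(1, 2), median)
  dimnames(rho) <- dimnames(counts)[c(1, 1)]
  if (length(constant)) {
    rho[constant, ] <- NA_real_
    rho[, constant] <- NA_real_
    diag(rho) <- 1
  }
  attr(rho, "undefined_taxa") <- constant
  rho
}

#' Bootstrap p-values for SparCC correlations
#'
#' Each bootstrap dataset permutes every taxon's counts independently across
#' samples (destroying all between-taxon association while keeping marginals),
#' recomputes the correlation matrix with a single estimation iteration, and
#' the p-value of a pair is the fraction of bootstrap datasets whose absolute
#' correlation reaches the observed one. With `n_boot = 1000` the strict
#' reading of "p < 0.001" means zero bootstrap exceedances; an optional
#' `(count + 1) / (n + 1)` estimator changes the attainable minimum.
#'
#' @param counts the count matrix used for the observed correlations.
#' @param observed_rho observed correlation matrix.
#' @param config a [jumbo_config()] list (`n_bootstrap`).
#' @param seed integer seed.
#' @param add_one use the `(count + 1) / (n + 1)` estimator.
#' @return Matrix of p-values (diagonal `NA`).
#' @export
bootstrap_pvalues <- function(counts, observed_rho, config = jumbo_config(),
                              seed = config$seed, add_one = FALSE) {
  counts <- as.matrix(counts)
  n_boot <- config$n_bootstrap
  if (n_boot < 1) stop("n_boot must be >= 1")
  D <- nrow(counts); n <- ncol(counts)
  set.seed(seed)
  exceed <- matrix(0L, D, D)
  obs <- abs(observed_rho)
  for (b in seq_len(n_boot)) {
    perm <- counts
    for (i in seq_len(D)) perm[i, ] <- perm[i, sample.int(n)]
    frac <- dirichlet_fractions(perm)
    rb <- abs(sparcc_once(frac, config))
    exceed <- exceed + (rb >= obs)
  }
  p <- if (add_one) (exceed + 1) / (n_boot + 1) else exceed / n_boot
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(observed_rho)
  p
}

#' Build the signed co-abundance network
#'
#' Retains pairs with `p < cutoff` (strict), signs them by the correlation,
#' and reports positive/negative edge counts.
#'
#' @param rho correlation matrix.
#' @param p p-value matrix.
#' @param config a [jumbo_config()] list (`p_cutoff`).
#' @return A list with `pairs` (data.frame `i, j, rho, p_value, sign`),
#'   `n_positive`, `n_negative`.
#' @export
build_coabundance_network <- function(rho, p, config = jumbo_config()) {
  D <- nrow(rho)
  ids <- rownames(rho)
  if (is.null(ids)) ids <- as.character(seq_len(D))
  out <- list()
  if (D >= 2) {
    for (i in seq_len(D - 1)) {
      for (j in (i + 1):D) {
        if (is.na(p[i, j]) || is.na(rho[i, j])) next
        if (p[i, j] < config$p_cutoff) {
          out[[length(out) + 1L]] <- data.frame(
            i = ids[i], j = ids[j], rho = rho[i, j], p_value = p[i, j],
            sign = ifelse(rho[i, j] >= 0, "positive", "negative"),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(i = character(), j = character(), rho = numeric(),
               p_value = numeric(), sign = character(), stringsAsFactors = FALSE)
  list(pairs = pairs,
       n_positive = sum(pairs$sign == "positive"),
       n_negative = sum(pairs$sign == "negative"))
}

#' Convert a zero-ruled abundance matrix to integer pseudo-counts
#'
#' Mean depths are scaled (x100 by default) and rounded so the Dirichlet
#' resampling of [sparcc_correlations()] is defined.
#'
#' @param abundance abundance matrix (genomes x samples).
#' @param config a [jumbo_config()] list (`pseudo_count_scale`).
#' @return Integer matrix.
#' @export
abundance_pseudo_counts <- function(abundance, config = jumbo_config()) {
  round(abundance * config$pseudo_count_scale)
}
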