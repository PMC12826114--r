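#' Detect orthologues between two proteomes (reciprocal best hits)
#'
#' Local alignment (Smith-Waterman, BLOSUM62) of every protein pair; hits are
#' kept at E-value <= 1e-5 (ungapped Karlin-Altschul), identity >= 30%, and
#' alignment coverage >= 50% of the shorter protein; orthologue pairs are the
#' reciprocal best hits (by raw score) among kept hits. Orthologous protein
#' clusters are realised as pairwise RBH sets rather than global clusters.
#'
#' @param proteome_a,proteome_b [Biostrings::AAStringSet] (or character
#'   vectors) of protein sequences; names default to indices.
#' @param config a [jumbo_config()] list.
#' @return A data.frame of orthologue pairs: `index_a`, `index_b`, `score`,
#'   `bits`, `identity`, `coverage`.
#' @export
detect_orthologues <- function(proteome_a, proteome_b, config = jumbo_config()) {
  a <- AAStringSet(proteome_a); b <- AAStringSet(proteome_b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("detect_orthologues requires non-empty proteomes")
  }
  S <- protein_score_matrix(a, b, config)
  la <- nchar(as.character(a)); lb <- nchar(as.character(b))
  E <- config$ka_k * outer(la, lb) * exp(-config$ka_lambda * S)
  S[E > config$rbh_max_evalue] <- -Inf
  empty <- data.frame(index_a = integer(), index_b = integer(),
                      score = numeric(), bits = numeric(),
                      identity = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE)
  if (all(!is.finite(S))) return(empty)
  best_for_a <- apply(S, 1, function(r) if (all(!is.finite(r))) NA_integer_ else which.max(r))
  best_for_b <- apply(S, 2, function(cl) if (all(!is.finite(cl))) NA_integer_ else which.max(cl))
  out <- list()
  for (i in seq_along(a)) {
    j <- best_for_a[i]
    if (is.na(j) || is.na(best_for_b[j]) || best_for_b[j] != i) next
    st <- protein_alignment_stats(as.character(a[[i]]), as.character(b[[j]]), config)
    if (st$identity < config$rbh_min_identity) next
    if (st$coverage < config$rbh_min_coverage) next
    out[[length(out) + 1L]] <- data.frame(
      index_a = i, index_b = j, score = st$score,
      bits = ka_bits(st$score, config),
      identity = st$identity, coverage = st$coverage,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Shared orthologue fraction between two proteomes
#'
#' The number of orthologue pairs divided by the size of the smaller proteome,
#' clamped to `[0, 1]`.
#'
#' @param pairs data.frame from [detect_orthologues()].
#' @param proteome_a,proteome_b the two proteomes.
#' @return A real in `[0, 1]`.
#' @export
shared_fraction <- function(pairs, proteome_a, proteome_b) {
  na <- length(AAStringSet(proteome_a)); nb <- length(AAStringSet(proteome_b))
  if (na == 0L || nb == 0L) stop("shared_fraction undefined for an empty proteome")
  min(nrow(pairs) / min(na, nb), 1)
}

#' Whole-proteome distance between two genomes
#'
#' Similarity is the sum of orthologue-pair alignment bit scores divided by the
#' smaller of the two proteome self-alignment bit-score totals, clamped to
#' `[0, 1]`; distance is one minus similarity. Identical proteomes are at
#' distance 0, proteomes with no orthologues at distance 1.
#'
#' @param pairs data.frame from [detect_orthologues()].
#' @param self_bits_a,self_bits_b total self-alignment bit scores of the two
#'   proteomes (see [proteome_self_bits()]).
#' @return A real in `[0, 1]`.
#' @export
proteomic_distance <- function(pairs, self_bits_a, self_bits_b) {
  if (self_bits_a <= 0 || self_bits_b <= 0) stop("zero self score")
  s <- sum(pairs$bits) / min(self_bits_a, self_bits_b)
  1 - min(max(s, 0), 1)
}

#' Total self-alignment bit score of a proteome
#' @param proteome an [Biostrings::AAStringSet] or character vector.
#' @param config a [jumbo_config()] list.
#' @return Sum over proteins of the bit score of each protein aligned to itself.
#' @export
proteome_self_bits <- function(proteome, config = jumbo_config()) {
  p <- AAStringSet(proteome)
  sum(vapply(seq_along(p), function(i) {
    ka_bits(self_alignment_score(p[[i]]), config)
  }, numeric(1)))
}

#' All-pairs orthologue and distance matrices for a set of proteomes
#'
#' @param proteomes named list of proteomes ([Biostrings::AAStringSet] or
#'   character vectors).
#' @param config a [jumbo_config()] list.
#' @return A list with `genome_ids`, symmetric `shared_fraction` and
#'   `n_orthologue_pairs` matrices (unit/size diagonal), and the symmetric
#'   `distance` matrix (zero diagonal).
#' @export
proteome_comparison <- function(proteomes, config = jumbo_config()) {
  ids <- names(proteomes)
  if (is.null(ids)) ids <- paste0("g", seq_along(proteomes))
  D <- length(proteomes)
  shared <- matrix(1, D, D, dimnames = list(ids, ids))
  npairs <- matrix(0L, D, D, dimnames = list(ids, ids))
  dist <- matrix(0, D, D, dimnames = list(ids, ids))
  self_bits <- vapply(proteomes, proteome_self_bits, numeric(1), config = config)
  for (i in seq_len(D)) {
    npairs[i, i] <- length(AAStringSet(proteomes[[i]]))
  }
  if (D >= 2) {
    for (i in seq_len(D - 1)) {
      for (j in (i + 1):D) {
        pr <- detect_orthologues(proteomes[[i]], proteomes[[j]], config)
        sf <- shared_fraction(pr, proteomes[[i]], proteomes[[j]])
        dd <- proteomic_distance(pr, self_bits[i], self_bits[j])
        shared[i, j] <- shared[j, i] <- sf
        npairs[i, j] <- npairs[j, i] <- nrow(pr)
        dist[i, j] <- dist[j, i] <- dd
      }
    }
  }
  list(genome_ids = ids, shared_fraction = shared,
       n_orthologue_pairs = npairs, distance = dist)
}

#' Build a neighbor-joining proteomic tree
#'
#' Neighbor-joining on a symmetric zero-diagonal distance matrix. For additive
#' matrices the patristic distances reproduce the input exactly. Negative
#' branch lengths (possible for non-additive input) are clamped to zero with
#' the deficit moved to the sibling edge.
#'
#' @param distance_matrix symmetric matrix with zero diagonal, >= 3 genomes.
#' @return A list with `tree` (an [ape::phylo]), `newick` string, and the
#'   `patristic` distance matrix.
#' @export
build_tree <- function(distance_matrix) {
  if (nrow(distance_matrix) < 3L) stop("build_tree requires >= 3 genomes")
  if (!isTRUE(all.equal(distance_matrix, t(distance_matrix)))) {
    stop("distance matrix must be symmetric")
  }
  tree <- ape::nj(distance_matrix)
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1]
    sib <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sib)) {
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + deficit
    }
  }
  list(tree = tree,
       newick = ape::write.tree(tree),
       patristic = stats::cophenetic(tree)[rownames(distance_matrix),
                                           rownames(distance_matrix)])
}

#' Demarcate families by the dual phylogenomic criterion
#'
#' Two genomes stay in the same family when they fail either prong of the
#' dual demarcation rule, i.e. they are "together" iff their patristic distance
#' on the proteomic tree is < 0.05 OR they share >= 10% of orthologous
#' proteins. Families are the connected components of the together-relation;
#' each family is labelled by its lexicographically smallest member.
#'
#' @param tree result of [build_tree()] (or any list with a `patristic`
#'   matrix).
#' @param orthologue_matrix result of [proteome_comparison()] (uses
#'   `shared_fraction`).
#' @param config a [jumbo_config()] list.
#' @return A data.frame `genome_id`, `family`.
#' @export
demarcate_families <- function(tree, orthologue_matrix, config = jumbo_config()) {
  ids <- orthologue_matrix$genome_ids
  P <- tree$patristic[ids, ids]
  SF <- orthologue_matrix$shared_fraction[ids, ids]
  together <- (P < config$family_min_distance) | (SF >= config$family_max_shared)
  diag(together) <- TRUE
  comp <- connected_components(together)
  fam <- vapply(split(ids, comp), function(members) min(members), "")
  data.frame(genome_id = ids, family = fam[as.character(comp)],
             row.names = NULL, stringsAsFactors = FALSE)
}

## connected components of a symmetric logical adjacency matrix (union-find)
connected_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(n)) {
    for (j in which(adj[i, ])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}
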