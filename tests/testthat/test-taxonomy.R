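rand_proteome <- function(n, len = 150:300) {
  vapply(seq_len(n), function(i) {
    aa <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
            "T","W","Y","V")
    paste(sample(aa, sample(len, 1), replace = TRUE), collapse = "")
  }, "")
}

test_that("orthologue detection: identical, disjoint and planted pairs", {
  set.seed(4)
  p <- rand_proteome(10)
  pairs <- detect_orthologues(p, p)
  expect_equal(nrow(pairs), 10L)
  expect_equal(shared_fraction(pairs, p, p), 1)
  ## disjoint random proteomes share nothing; confirm no alignment passes the
  ## thresholds by checking the best cross-pair E-value directly
  q <- rand_proteome(10)
  pq <- detect_orthologues(p, q)
  expect_equal(nrow(pq), 0L)
  cfg <- jumbo_config()
  best_e <- min(vapply(seq_along(p), function(i) {
    min(vapply(seq_along(q), function(j) {
      st <- jumbophage:::protein_alignment_stats(p[i], q[j], cfg)
      ka_evalue(st$score, nchar(p[i]), nchar(q[j]), config = cfg)
    }, 0))
  }, 0))
  expect_gt(best_e, cfg$rbh_max_evalue)
  ## one planted orthologue at ~95% identity
  q2 <- q
  q2[3] <- jumbophage:::mutate_protein(p[5], rate = 0.05)
  pq2 <- detect_orthologues(p, q2)
  expect_equal(nrow(pq2), 1L)
  expect_equal(pq2$index_a, 5L)
  expect_equal(pq2$index_b, 3L)
  expect_gte(pq2$identity, 0.30)
  expect_gte(pq2$coverage, 0.50)
})

test_that("shared fraction uses the smaller proteome as denominator", {
  set.seed(5)
  small <- rand_proteome(10)
  big <- c(small, rand_proteome(30))
  pairs <- detect_orthologues(small, big)
  expect_equal(nrow(pairs), 10L)
  expect_equal(shared_fraction(pairs, small, big), 1)
  expect_equal(shared_fraction(pairs[0, ], small, big), 0)
  ## 3 pairs over proteomes of 30 and 60 -> exactly the 0.10 boundary
  expect_equal(shared_fraction(data.frame(i = 1:3), rand_proteome(30),
                               rand_proteome(60)), 0.1)
  expect_error(shared_fraction(pairs, character(0), big), "empty")
})

test_that("proteomic distance is 0 for identical, 1 for disjoint, monotone", {
  set.seed(6)
  p <- rand_proteome(12)
  sb <- proteome_self_bits(p)
  expect_equal(proteomic_distance(detect_orthologues(p, p), sb, sb), 0)
  q <- rand_proteome(12)
  expect_equal(proteomic_distance(detect_orthologues(p, q), sb,
                                  proteome_self_bits(q)), 1)
  ## distance decreases as sharing grows
  d <- vapply(c(2, 5, 9), function(k) {
    mixed <- c(p[seq_len(k)], rand_proteome(12 - k))
    proteomic_distance(detect_orthologues(p, mixed), sb,
                       proteome_self_bits(mixed))
  }, 0)
  expect_true(all(diff(d) < 0))
  expect_error(proteomic_distance(data.frame(bits = 1), 0, 1), "zero self")
})

test_that("neighbor joining reproduces additive distances exactly", {
  ## closed form on 3 taxa: d(A,B)=2, d(A,C)=d(B,C)=6 -> branches 1,1,5
  d3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- build_tree(d3)
  expect_equal(sort(tr3$tree$edge.length), c(1, 1, 5))
  expect_equal(tr3$patristic, d3)
  expect_match(tr3$newick, "^\\(")
  ## random additive matrices on 4-6 taxa: patristic == input to 1e-9
  for (n in 4:6) {
    dm <- oracle_additive_matrix(n, seed = n * 11)
    tr <- build_tree(dm)
    expect_lt(max(abs(tr$patristic[rownames(dm), colnames(dm)] - dm)), 1e-9)
  }
  expect_error(build_tree(d3[1:2, 1:2]), ">= 3")
})

test_that("family demarcation separates planted families and respects the
           0.10 sharing boundary", {
  set.seed(8)
  pf <- generate_proteome_families(c(3, 3), within = 0.6, between = 0,
                                   proteome_size = 20, seed = 2)
  cmp <- proteome_comparison(pf$proteomes)
  tree <- build_tree(cmp$distance)
  fam <- demarcate_families(tree, cmp)
  m <- merge(fam, pf$truth, by = "genome_id")
  expect_equal(length(unique(fam$family)), 2L)
  tab <- table(m$family, m$family_planted)
  expect_true(all(rowSums(tab > 0) == 1))  # partitions coincide
  ## genome order must not matter
  perm <- sample(length(pf$proteomes))
  cmp2 <- proteome_comparison(pf$proteomes[perm])
  fam2 <- demarcate_families(build_tree(cmp2$distance), cmp2)
  m12 <- merge(fam, fam2, by = "genome_id")
  expect_true(jumbophage:::partition_identical(m12$family.x, m12$family.y))
  ## shared fraction exactly 0.10 keeps a pair together even at distance
  ids <- c("a", "b", "c")
  P <- matrix(1, 3, 3, dimnames = list(ids, ids)); diag(P) <- 0
  SF <- matrix(0, 3, 3, dimnames = list(ids, ids)); diag(SF) <- 1
  SF["a", "b"] <- SF["b", "a"] <- 0.10
  fake_cmp <- list(genome_ids = ids, shared_fraction = SF)
  fam3 <- demarcate_families(list(patristic = P), fake_cmp)
  expect_equal(fam3$family[fam3$genome_id == "a"],
               fam3$family[fam3$genome_id == "b"])
  expect_equal(length(unique(fam3$family)), 2L)
  ## all genomes identical -> a single family
  SF1 <- matrix(1, 3, 3, dimnames = list(ids, ids))
  P0 <- matrix(0, 3, 3, dimnames = list(ids, ids))
  fam4 <- demarcate_families(list(patristic = P0),
                             list(genome_ids = ids, shared_fraction = SF1))
  expect_equal(length(unique(fam4$family)), 1L)
})

test_that("family count is monotone as the sharing threshold loosens", {
  set.seed(12)
  pf <- generate_proteome_families(c(2, 2, 2), within = 0.5, between = 0,
                                   proteome_size = 16, seed = 5)
  cmp <- proteome_comparison(pf$proteomes)
  tree <- build_tree(cmp$distance)
  counts <- vapply(c(0.05, 0.2, 0.45, 0.6), function(th) {
    length(unique(demarcate_families(tree, cmp,
                                     jumbo_config(family_max_shared = th))$family))
  }, 1L)
  expect_true(all(diff(counts) >= 0))
})
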