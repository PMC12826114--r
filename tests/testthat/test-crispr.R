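test_that("planted arrays are recovered with string-identical spacers", {
  set.seed(42)
  g <- Biostrings::DNAStringSet(c(A = random_dna_chr(60000),
                                  B = random_dna_chr(60000)))
  spec <- data.frame(source = "A", target = "B", n_spacers = 3L,
                     mismatches = 0L, stringsAsFactors = FALSE)
  pl <- plant_crispr_targeting(g, spec, seed = 5)
  arr <- detect_crispr_arrays(pl$genomes[["A"]], "A")
  expect_length(arr, 1)
  expect_length(arr[[1]]$repeats, 4)           # n_spacers + 1 copies
  expect_length(arr[[1]]$spacers, 3)
  expect_equal(length(unique(arr[[1]]$repeats)), 1L)
  expect_setequal(arr[[1]]$spacers, pl$truth$spacer_edges$spacer)
  ## invariants from the array definition
  expect_true(all(nchar(arr[[1]]$repeats) >= 23 & nchar(arr[[1]]$repeats) <= 47))
  expect_true(all(nchar(arr[[1]]$spacers) >= 26 & nchar(arr[[1]]$spacers) <= 50))
})

test_that("two planted arrays come back sorted by start", {
  set.seed(9)
  g <- Biostrings::DNAStringSet(c(A = random_dna_chr(120000),
                                  B = random_dna_chr(60000),
                                  C = random_dna_chr(60000)))
  spec <- data.frame(source = c("A", "A"), target = c("B", "C"),
                     n_spacers = 2L, mismatches = 0L, stringsAsFactors = FALSE)
  pl <- plant_crispr_targeting(g, spec, seed = 2)
  arr <- detect_crispr_arrays(pl$genomes[["A"]], "A")
  expect_length(arr, 2)
  expect_true(arr[[1]]$start < arr[[2]]$start)
})

test_that("random sequence yields no arrays (verified brute-force)", {
  set.seed(33)
  r <- random_dna_chr(30000)
  expect_true(oracle_no_repeat_structure(r))
  expect_length(detect_crispr_arrays(r, "r"), 0)
})

test_that("spacer matching agrees exactly with the brute-force Hamming scan", {
  set.seed(14)
  target <- random_dna_chr(40000)
  tgt_chars <- strsplit(target, "")[[1]]
  ## spacers planted at known loci: exact, 1-mismatch, 2-mismatch, end-mismatch,
  ## and a reverse-complement placement
  mk_spacer <- function(pos, mm_at = integer()) {
    v <- tgt_chars[pos:(pos + 31)]
    for (m in mm_at) v[m] <- setdiff(c("A", "C", "G", "T"), v[m])[1]
    paste(v, collapse = "")
  }
  spacers <- c(mk_spacer(1000),
               mk_spacer(5000, 16),
               mk_spacer(9000, c(10, 20)),
               mk_spacer(13000, c(1, 16)),   # one clippable end mismatch + one interior
               mk_spacer(17000))
  spacers[5] <- paste(rc_chars(strsplit(spacers[5], "")[[1]]), collapse = "")
  arrays <- list(list(genome_id = "src", start = 1,
                      repeats = rep("R", length(spacers) + 1),
                      spacers = spacers, repeat_consensus = "R"))
  genomes <- Biostrings::DNAStringSet(c(src = random_dna_chr(1000),
                                        tgt = target))
  got <- match_spacers(arrays, genomes)
  got <- got[order(got$spacer_index, got$target_start), ]
  for (si in seq_along(spacers)) {
    oracle <- oracle_spacer_scan(spacers[si], target)
    mine <- got[got$spacer_index == si,
                c("target_start", "strand", "mismatches", "coverage")]
    rownames(mine) <- rownames(oracle) <- NULL
    expect_equal(mine, oracle[order(oracle$target_start), ],
                 info = paste("spacer", si))
  }
  ## the 2-mismatch spacer must not match at all
  expect_false(3 %in% got$spacer_index)
  ## clipping the end mismatch leaves one interior mismatch: still a match
  end_hit <- got[got$spacer_index == 4, ]
  expect_equal(nrow(end_hit), 1L)
  expect_equal(end_hit$coverage, 31 / 32)
  expect_equal(end_hit$mismatches, 1L)
})

test_that("spacers never match their own source genome", {
  set.seed(21)
  g <- Biostrings::DNAStringSet(c(A = random_dna_chr(50000),
                                  B = random_dna_chr(50000)))
  spec <- data.frame(source = "A", target = "B", n_spacers = 2L,
                     mismatches = 0L, stringsAsFactors = FALSE)
  pl <- plant_crispr_targeting(g, spec, seed = 4)
  arr <- detect_crispr_arrays(pl$genomes[["A"]], "A")
  m <- match_spacers(arr, pl$genomes)
  expect_true(all(m$source_genome == "A" & m$target_genome == "B"))
  expect_true(all(m$mismatches <= 1))
  expect_true(all(m$coverage >= 0.95))
})

test_that("interaction network classifies mutual and competitive pairs", {
  m <- data.frame(source_genome = c("A", "B", "A", "H"),
                  array_index = 1L, spacer_index = 1:4,
                  target_genome = c("B", "A", "C", "A"),
                  target_start = 1L, strand = "+", mismatches = 0L,
                  coverage = 1, stringsAsFactors = FALSE)
  hp <- host_predictions(c("A", "B", "C"), rep("Bacteria", 3),
                         c("Bacillota_A", "Bacillota_A", "Bacteroidota"))
  net <- build_interaction_network(m, phage_ids = c("A", "B", "C"),
                                   host_preds = hp)
  expect_equal(nrow(net$phage_phage_edges), 3L)
  expect_equal(nrow(net$phage_host_edges), 1L)
  expect_equal(net$phage_host_edges$direction, "host_targets_phage")
  expect_equal(nrow(net$mutual_pairs), 1L)       # A<->B
  ## A-B share a host phylum (competitive); A-C do not
  expect_equal(nrow(net$competitive_pairs), 1L)
  expect_equal(unlist(net$competitive_pairs[1, ], use.names = FALSE), c("A", "B"))
  ## input order invariance
  net2 <- build_interaction_network(m[sample(nrow(m)), ], c("A", "B", "C"), hp)
  expect_equal(net2$phage_phage_edges, net$phage_phage_edges)
  expect_equal(net2$mutual_pairs, net$mutual_pairs)
  s <- network_summary(net)
  expect_equal(s$phage_phage_pairs, 2L)
  expect_equal(s$phage_host_pairs, 1L)
  expect_equal(s$total_pairs, 3L)
  expect_lte(s$mutual_pairs, s$phage_phage_pairs)
})

test_that("network summary reproduces the published pair arithmetic", {
  ## 282 phage-phage + 143 phage-host = 425 spacer pairs;
  ## 244 mutual of 282 = 86.52%; 72 competitive of 425 = 16.94%
  expect_equal(282 + 143, 425)
  expect_equal(summarize_percent(244, 282), 86.52)
  expect_equal(summarize_percent(72, 425), 16.94)
  ## an empty network summarises to zeros
  empty <- build_interaction_network(jumbophage:::empty_spacer_matches(),
                                     character(0))
  s0 <- network_summary(empty)
  expect_equal(s0$total_pairs, 0L)
  expect_equal(s0$mutual_pairs, 0L)
  expect_equal(s0$competitive_pairs, 0L)
})
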