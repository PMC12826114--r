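test_that("community generation: labels, determinism, degenerate input", {
  c1 <- generate_community(3, 2, seed = 1)
  expect_length(c1$genomes, 5)
  expect_equal(sum(c1$truth$labels$is_phage), 3L)
  expect_equal(sum(!c1$truth$labels$is_phage), 2L)
  expect_true(all(Biostrings::width(c1$genomes) > 200000))
  ## gene tables are consistent with the sequences
  expect_silent(jumbophage:::validate_annotations(c1$annotations, c1$genomes))
  ## contaminants exceed the BUSCO bound, phages sit below it
  lab <- c1$truth$labels
  expect_true(all(lab$busco_ratio_planted[!lab$is_phage] > 0.067))
  expect_true(all(lab$busco_ratio_planted[lab$is_phage] < 0.067))
  ## determinism: identical seed, identical bytes
  c2 <- generate_community(3, 2, seed = 1)
  expect_identical(as.character(c1$genomes), as.character(c2$genomes))
  expect_identical(c1$annotations, c2$annotations)
  ## empty community
  c0 <- generate_community(0, 0, seed = 1)
  expect_length(c0$genomes, 0)
  expect_equal(nrow(c0$annotations), 0L)
})

test_that("recoded genomes carry the planted density margin", {
  rg <- generate_recoded_genome(15, 80000, seed = 7)
  expect_gte(rg$densities[["15"]], 1.10 * rg$densities[["11"]])
  rg11 <- generate_recoded_genome(11, 80000, seed = 7)
  gains <- rg11$densities[c("15", "90", "91")] / rg11$densities[["11"]]
  expect_true(all(gains < 1.10))
  expect_error(generate_recoded_genome(15, 300, seed = 1), "larger length")
  expect_error(generate_recoded_genome(14, 80000), "unknown genetic code")
})

test_that("planted spacers carry exactly the requested Hamming distance", {
  set.seed(2)
  g <- Biostrings::DNAStringSet(c(A = random_dna_chr(60000),
                                  B = random_dna_chr(60000)))
  spec <- data.frame(source = "A", target = "B", n_spacers = 2L,
                     mismatches = 2L, stringsAsFactors = FALSE)
  pl <- plant_crispr_targeting(g, spec, seed = 3)
  tr <- pl$truth$spacer_edges
  tgt <- as.character(pl$genomes[["B"]])
  for (r in seq_len(nrow(tr))) {
    proto <- substr(tgt, tr$protospacer_start[r],
                    tr$protospacer_start[r] + nchar(tr$spacer[r]) - 1L)
    hd <- sum(strsplit(proto, "")[[1]] != strsplit(tr$spacer[r], "")[[1]])
    expect_equal(hd, 2L)
  }
  ## empty edge spec leaves genomes untouched
  pl0 <- plant_crispr_targeting(g, spec[0, ], seed = 3)
  expect_identical(as.character(pl0$genomes), as.character(g))
  expect_error(plant_crispr_targeting(g, data.frame(source = "A", target = "B",
                                                    n_spacers = 1L,
                                                    mismatches = 40L), 1),
               "exceed")
})

test_that("proteome families have the requested sharing structure", {
  pf <- generate_proteome_families(c(3, 3), within = 0.6, between = 0,
                                   proteome_size = 20, seed = 2)
  expect_length(pf$proteomes, 6)
  ## measured by counting planted near-identical copies directly: within-family
  ## pairs share >= 0.6, between-family pairs share 0
  sim_count <- function(a, b) {
    shared <- 0L
    for (x in a) {
      d <- vapply(b, function(y) {
        if (nchar(x) != nchar(y)) return(1)
        mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
      }, 0)
      if (any(d <= 0.05)) shared <- shared + 1L
    }
    shared
  }
  within <- sim_count(pf$proteomes[["F1_g1"]], pf$proteomes[["F1_g2"]]) / 20
  between <- sim_count(pf$proteomes[["F1_g1"]], pf$proteomes[["F2_g1"]]) / 20
  expect_gte(within, 0.6)
  expect_equal(between, 0)
  ## identical proteomes share everything
  p <- pf$proteomes[["F1_g1"]]
  expect_equal(sim_count(p, p) / 20, 1)
  expect_error(generate_proteome_families(c(2, 2), within = 0.1, between = 0.5),
               "must exceed")
})

test_that("abundance generator plants latent correlations as labelled", {
  ab <- generate_abundance_matrix(10, 200, data.frame(i = 1, j = 2, sign = "+"),
                                  seed = 3)
  expect_gt(cor(ab$latent[1, ], ab$latent[2, ]), 0.8)
  ## unplanted pairs stay weak at this sample size
  off <- cor(t(ab$latent[3:10, ]))
  expect_lt(max(abs(off[upper.tri(off)])), 0.3)
  expect_equal(dim(ab$counts), c(10L, 200L))
  expect_true(all(colSums(ab$counts) == 1e5))
  ## determinism
  ab2 <- generate_abundance_matrix(10, 200,
                                   data.frame(i = 1, j = 2, sign = "+"),
                                   seed = 3)
  expect_identical(ab$counts, ab2$counts)
})
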