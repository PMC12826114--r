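## hand-built fixture: poly-C flanks carry no start/stop codons on either
## strand, so the only ORFs are the planted ones
polyC <- function(n) strrep("C", n)

test_that("ORF scan finds the planted gene with the right span per code", {
  gene <- paste0("ATG", strrep("AAA", 40), "TAA", "TAG")
  g <- paste0(polyC(300), gene, polyC(300))
  ## codes whose stop set retains TAA terminate at it: span 126 nt
  for (cd in c(11, 15, 91)) {
    o <- find_orfs(g, cd)
    expect_equal(nrow(o$orfs), 1L)
    expect_equal(o$orfs$end - o$orfs$start + 1L, 126L)
    expect_equal(o$orfs$strand, "+")
    expect_equal(o$coded_fraction, 126 / nchar(g))
  }
  ## code 90 reassigns TAA: the ORF runs on to the trailing TAG
  ## (ATG + 40 codons + TAA-as-sense + TAG = 43 codons = 129 nt)
  o90 <- find_orfs(g, 90)
  expect_equal(o90$orfs$end - o90$orfs$start + 1L, 129L)
})

test_that("an in-frame TAG splits the gene under code 11 but not code 15", {
  ## 50 codons, TAG at the midpoint followed by a new ATG start
  gene <- paste0("ATG", strrep("AAA", 48), "TAG",
                 "ATG", strrep("AAA", 48), "TGA")
  g <- paste0(polyC(120), gene, polyC(120))
  o11 <- find_orfs(g, 11)
  expect_equal(nrow(o11$orfs), 2L)
  expect_equal(sort(o11$orfs$end - o11$orfs$start + 1L), c(150L, 150L))
  o15 <- find_orfs(g, 15)  # TAG is not a stop: one long ORF
  expect_equal(nrow(o15$orfs), 1L)
  expect_equal(o15$orfs$end - o15$orfs$start + 1L, 300L)
})

test_that("degenerate ORF inputs", {
  expect_equal(find_orfs(strrep("N", 500), 11)$coded_fraction, 0)
  short <- find_orfs("ATGAAATAA", 11)
  expect_equal(nrow(short$orfs), 0L)
  expect_equal(short$coded_fraction, 0)
})

test_that("removing a stop codon never decreases coded fraction", {
  set.seed(7)
  for (i in 1:5) {
    g <- random_dna_chr(6000)
    d11 <- find_orfs(g, 11)$coded_fraction
    for (cd in c(15, 90, 91)) {
      expect_gte(find_orfs(g, cd)$coded_fraction, d11)
    }
  }
})

test_that("code assignment needs a >= 10% density gain", {
  ## planted alternative codes are recovered
  rg <- generate_recoded_genome(15, 80000, seed = 7)
  expect_equal(assign_genetic_code(rg$genome[[1]])$assigned_code, 15L)
  rg90 <- generate_recoded_genome(90, 80000, seed = 8)
  expect_equal(assign_genetic_code(rg90$genome[[1]])$assigned_code, 90L)
  ## a standard-code genome stays at 11
  rg11 <- generate_recoded_genome(11, 80000, seed = 9)
  expect_equal(assign_genetic_code(rg11$genome[[1]])$assigned_code, 11L)
})

test_that("a gain just below the margin keeps code 11", {
  ## single gene: ATG + 999 no-stop/no-start codons + TAG + tail + TAA.
  ## code 11 stops at the TAG (3003 nt); code 15 reads through to the TAA.
  ## tail codons (CCC) contain no start, so code 11 gains no second ORF.
  gene_body <- strrep("AAA", 999)
  below <- paste0(polyC(300), "ATG", gene_body, "TAG", strrep("CCC", 98), "TAA",
                  polyC(300))
  a <- assign_genetic_code(below)
  ## code-15 span 3300 nt vs code-11 span 3003 nt: gain 9.89% < 10%
  expect_equal(a$densities[["15"]] / a$densities[["11"]], 3300 / 3003)
  expect_equal(a$assigned_code, 11L)
  above <- paste0(polyC(300), "ATG", gene_body, "TAG", strrep("CCC", 110), "TAA",
                  polyC(300))
  a2 <- assign_genetic_code(above)
  ## span 3336 vs 3003: gain 11.09% >= 10%
  expect_equal(a2$densities[["15"]] / a2$densities[["11"]], 3336 / 3003)
  expect_equal(a2$assigned_code, 15L)
})

test_that("code assignment is invariant to reverse complement", {
  rg <- generate_recoded_genome(15, 60000, seed = 3)
  fwd <- assign_genetic_code(rg$genome[[1]])
  rev <- assign_genetic_code(Biostrings::reverseComplement(rg$genome[[1]]))
  expect_equal(fwd$assigned_code, rev$assigned_code)
  expect_equal(fwd$densities, rev$densities)
})

test_that("crAss classification by marker homology and reference identity", {
  mk <- load_crass_markers()
  set.seed(10)
  g <- Biostrings::DNAStringSet(c(X = random_dna_chr(80000)))
  g <- jumbophage:::plant_cursor(g)
  g <- jumbophage:::write_at_cursor(
    g, "X", jumbophage:::reverse_translate(as.character(mk[["terminase"]])))
  cc <- crass_classify(g[["X"]], mk)
  expect_true(cc$hit_terminase)
  expect_false(cc$hit_polymerase)
  expect_lt(cc$best_evalue, 1e-10)
  expect_true(cc$is_crass)
  ## a random genome with no markers is rejected
  r <- random_dna_chr(80000)
  cc2 <- crass_classify(r, mk)
  expect_false(cc2$is_crass)
  expect_gt(cc2$best_evalue, 1e-10)
  ## the reference genome matches itself completely
  cc3 <- crass_classify(r, mk, reference_genome = r)
  expect_equal(cc3$nt_identity, 1)
  expect_equal(cc3$aligned_fraction, 1)
  expect_true(cc3$is_crass)
  ## criterion 2 is reported unevaluated without a reference
  expect_true(is.na(cc2$nt_identity))
  ## the 70 kb gate
  cc4 <- crass_classify(random_dna_chr(60000), mk)
  expect_false(cc4$is_crass)
  expect_equal(cc4$reason, "size")
})
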