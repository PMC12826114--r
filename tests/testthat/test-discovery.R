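mk_ann <- function(n, viral_frac = 0, microbial_frac = 0, strand_run = 0,
                   products = NULL, busco_hits = 0) {
  strand <- sample(c("+", "-"), n, replace = TRUE)
  if (strand_run > 0) strand[1:strand_run] <- "+"
  labels <- rep("none", n)
  if (viral_frac > 0) labels[seq_len(round(viral_frac * n))] <- "viral_family"
  if (microbial_frac > 0) {
    labels[seq_len(round(microbial_frac * n))] <- "microbial_family"
  }
  data.frame(genome_id = rep("g", n), gene_index = seq_len(n),
             start = seq(1, by = 1000, length.out = n),
             end = seq(900, by = 1000, length.out = n),
             strand = strand,
             protein = rep("M", n),
             product_text = if (is.null(products)) rep("hypothetical protein", n)
                            else rep_len(products, n),
             hit_labels = labels,
             busco_hit = c(rep(TRUE, busco_hits), rep(FALSE, n - busco_hits)),
             stringsAsFactors = FALSE)
}

test_that("viral signatures count flags per the documented thresholds", {
  set.seed(1)
  ann <- mk_ann(40, viral_frac = 0.3, strand_run = 12)
  s <- score_viral_signatures("ACGT", ann)
  expect_true(s$has_viral_families)
  expect_true(s$lacks_microbial_families)
  expect_true(s$has_strand_runs)
  expect_gte(s$n_signatures, 3)
  ## zero annotated genes: only the (default absent) nucleotide signature
  s0 <- score_viral_signatures("ACGT", mk_ann(0))
  expect_equal(s0$n_signatures, 0L)
  expect_false(s0$has_viral_families)
  ## all-microbial annotations
  sm <- score_viral_signatures("ACGT", mk_ann(20, microbial_frac = 1))
  expect_false(sm$has_viral_families)
  expect_false(sm$lacks_microbial_families)
  ## pluggable nucleotide-signature predicate
  cfg <- jumbo_config(nt_signature_fun = function(g) TRUE)
  expect_true(score_viral_signatures("ACGT", mk_ann(0), cfg)$has_viral_nt_signature)
})

test_that("keyword phage rule needs 2 keywords, no exclusions, spacer evidence", {
  ann <- mk_ann(10, products = c("terminase large subunit",
                                 "major capsid protein",
                                 rep("hypothetical protein", 8)))
  call <- call_phage("g", ann, spacer_evidence = TRUE, genome_length = 250000)
  expect_true(call$is_phage)
  expect_equal(call$n_keyword_genes, 2L)
  expect_true(call$is_jumbo)
  ## an exclusion term vetoes even keyword-rich genomes
  ann2 <- mk_ann(10, products = c("terminase", "capsid", "portal", "tail fiber",
                                  "holin", "DNA gyrase subunit A",
                                  rep("x", 4)))
  expect_false(call_phage("g", ann2, TRUE, 250000)$is_phage)
  ## one keyword gene is not enough
  ann3 <- mk_ann(10, products = c("major capsid protein",
                                  rep("hypothetical protein", 9)))
  expect_false(call_phage("g", ann3, TRUE, 250000)$is_phage)
  ## no spacer evidence
  expect_false(call_phage("g", ann, FALSE, 250000)$is_phage)
  ## keyword matching is case-insensitive substring
  ann4 <- mk_ann(10, products = c("Phage TAIL protein", "PORTAL vertex",
                                  rep("y", 8)))
  expect_true(call_phage("g", ann4, TRUE, 250000)$is_phage)
  ## 200 kb boundary is strict
  expect_false(call_phage("g", ann, TRUE, 200000)$is_jumbo)
  expect_true(call_phage("g", ann, TRUE, 200001)$is_jumbo)
})

test_that("BUSCO ratio boundary is strict and well-behaved", {
  expect_false(busco_filter(mk_ann(149, busco_hits = 10))$passes_busco) # 0.0671
  expect_true(busco_filter(mk_ann(151, busco_hits = 10))$passes_busco)  # 0.0662
  z <- busco_filter(mk_ann(150, busco_hits = 0))
  expect_equal(z$busco_ratio, 0)
  expect_true(z$passes_busco)
  expect_error(busco_filter(mk_ann(0)), "zero genes")
  ## exactly 0.067 fails (strict <): 67/1000
  expect_false(busco_filter(mk_ann(1000, busco_hits = 67))$passes_busco)
  ## invariant under gene reordering; monotone in hits
  a <- mk_ann(60, busco_hits = 3)
  expect_equal(busco_filter(a)$busco_ratio,
               busco_filter(a[sample(nrow(a)), ])$busco_ratio)
  r <- vapply(0:6, function(h) busco_filter(mk_ann(60, busco_hits = h))$busco_ratio, 0)
  expect_true(all(diff(r) > 0))
})

test_that("lifestyle assignment follows score cuts with provirus override", {
  expect_equal(assign_lifestyle(0.2, FALSE)$lifestyle, "virulent")
  expect_equal(assign_lifestyle(0.2, TRUE)$lifestyle, "temperate")
  expect_equal(assign_lifestyle(0.95, FALSE)$lifestyle, "temperate")
  ## boundary values fall in the uncertain (closed) interval
  expect_equal(assign_lifestyle(0.5, FALSE)$lifestyle, "uncertain")
  expect_equal(assign_lifestyle(0.9, FALSE)$lifestyle, "uncertain")
  expect_error(assign_lifestyle(1.2, FALSE), "outside")
  expect_error(assign_lifestyle(-0.1, FALSE), "outside")
})

test_that("host breadth classification", {
  hp <- host_predictions(c("p1", "p1", "p2", "p3"),
                         c("Bacteria", "Bacteria", "Archaea", "Bacteria"),
                         c("Bacillota_A", "Bacteroidota",
                           "Methanobacteriota", "Bacillota_A"))
  cls <- classify_host_breadth(hp, c("p1", "p2", "p3", "p4"))
  expect_equal(cls$breadth_class,
               c("generalist", "archaeal", "specialist", "unknown"))
})

test_that("summarize_percent uses half-up rounding and complements to 100", {
  expect_equal(summarize_percent(53, 1545), 3.43)
  expect_equal(summarize_percent(1536, 1545), 99.42)
  expect_equal(summarize_percent(0, 10), 0)
  expect_error(summarize_percent(1, 0), "positive")
  expect_error(summarize_percent(5, 3), "outside")
  ## complement property up to one rounding ulp
  set.seed(2)
  for (i in 1:50) {
    total <- sample(1:5000, 1); count <- sample(0:total, 1)
    s <- summarize_percent(count, total) + summarize_percent(total - count, total)
    expect_lte(abs(s - 100), 0.01)
  }
})
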