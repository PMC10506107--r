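test_that("generators are deterministic under (seed, spec)", {
  spec <- synthetic_spec(seed = 41, n_reads = 2000L)
  tx1 <- make_transcript(spec)
  tx2 <- make_transcript(spec)
  expect_identical(tx1$transcript$seq, tx2$transcript$seq)

  f1 <- simulate_footprints(tx1$transcript, tx1$annotation, spec)
  f2 <- simulate_footprints(tx2$transcript, tx2$annotation, spec)
  expect_identical(f1$reads, f2$reads)

  expect_identical(simulate_luciferase(spec)$table,
                   simulate_luciferase(spec)$table)
  expect_identical(simulate_ortholog_peptides(spec, "MKLVAG")$peptides,
                   simulate_ortholog_peptides(spec, "MKLVAG")$peptides)

  # a different seed changes the draw
  spec2 <- synthetic_spec(seed = 42, n_reads = 2000L)
  expect_false(identical(make_transcript(spec2)$transcript$seq,
                         tx1$transcript$seq))
})

test_that("generated transcripts carry the planted downstream stop", {
  tx <- make_transcript(synthetic_spec(seed = 43, isr_len = 267L))
  expect_equal(tx$annotation$extension_len_aa, 89L)

  set.seed(44)
  for (i in 1:100) {
    spec <- synthetic_spec(seed = 5000L + i,
                           utr5_len = sample(30:150, 1),
                           cds_len = 3L * sample(20:120, 1),
                           isr_len = 3L * sample(4:120, 1),
                           utr3_rest_len = sample(30:400, 1))
    tx <- make_transcript(spec)
    a <- tx$annotation
    expect_equal(a$stop2_start, tx$transcript$cds_end + spec$isr_len)
    expect_equal(a$stop2_start,
                 oracle_scan_stop2(tx$transcript$seq, tx$transcript$cds_end))
  }
})

test_that("footprint intensity model has the stated expected densities", {
  # unscaled intensities: r = 0 makes the ISR window pure background
  tx <- make_transcript(synthetic_spec(seed = 45))
  spec0 <- synthetic_spec(seed = 45, readthrough_fraction = 0, n_reads = NULL)
  sim0 <- simulate_footprints(tx$transcript, tx$annotation, spec0)
  expect_equal(sim0$truth$expected_density$isr_window,
               spec0$background_density)

  # r = 0.1, d = 0.05, b = 0 gives an expected ISR density of 0.005
  spec1 <- synthetic_spec(seed = 45, readthrough_fraction = 0.1,
                          background_density = 0, n_reads = NULL)
  sim1 <- simulate_footprints(tx$transcript, tx$annotation, spec1)
  expect_equal(sim1$truth$expected_density$isr_window, 0.005)
  expect_equal(sim1$truth$expected_density$three_utr_rest, 0)
})

test_that("scaled libraries hit the requested size in expectation", {
  tx <- make_transcript(synthetic_spec(seed = 46))
  spec <- synthetic_spec(seed = 46, n_reads = 30000L)
  sim <- simulate_footprints(tx$transcript, tx$annotation, spec)
  expect_lt(abs(nrow(sim$reads) - 30000), 4 * sqrt(30000))
  expect_equal(sum(unlist(sim$truth$expected_region_counts)), 30000,
               tolerance = 1e-6)
})

test_that("count-level sampling follows the intensity model", {
  tx <- make_transcript(synthetic_spec(seed = 47))
  spec <- synthetic_spec(seed = 47, n_reads = 50000L)
  tabs <- simulate_region_counts(tx$transcript, tx$annotation, spec,
                                 n_datasets = 40)
  expect_length(tabs, 40L)
  # expected counts straight from the piecewise-constant intensities
  sch <- build_region_scheme(tx$transcript, tx$annotation)
  intensity <- c(five_utr = spec$background_density,
                 cds_body = spec$cds_density,
                 isr_window = spec$background_density +
                   spec$readthrough_fraction * spec$cds_density,
                 three_utr_rest = spec$background_density)
  lam <- intensity[sch$region] * sch$length
  lam <- lam * spec$n_reads / sum(lam)
  for (region in c("cds_body", "isr_window", "three_utr_rest")) {
    mu <- mean(vapply(tabs, function(tb)
      tb$regions$read_count[tb$regions$region == region], numeric(1)))
    expected <- lam[[region]]
    expect_lt(abs(mu - expected), 4 * sqrt(expected / 40) + 1)
  }
  # densities divide by the same region lengths the analysis uses
  expect_equal(tabs[[1]]$regions$region_len, sch$length)
})

test_that("luciferase simulation recovers the designed readthrough in the noiseless limit", {
  spec <- synthetic_spec(seed = 48, noise_sigma = 0, true_percent = 11.1)
  sim <- simulate_luciferase(spec)
  est <- percent_tcr_from_table(sim$table, "with_stop", "no_stop")
  expect_equal(est$percent_tcr, 11.1, tolerance = 1e-12)

  # designed efficiency of 100% makes both constructs identical in law
  spec100 <- synthetic_spec(seed = 48, noise_sigma = 0, true_percent = 100)
  est100 <- percent_tcr_from_table(simulate_luciferase(spec100)$table,
                                   "with_stop", "no_stop")
  expect_equal(est100$percent_tcr, 100, tolerance = 1e-12)
})

test_that("ortholog panels respect the substitution model", {
  spec0 <- synthetic_spec(seed = 49, substitution_prob = 0)
  sim0 <- simulate_ortholog_peptides(spec0, "MKLVAGHTSW")
  expect_true(all(sim0$peptides == "MKLVAGHTSW"))
  prof <- score_conservation(sim0$peptides, prealigned = TRUE)
  expect_true(all(prof$column_identity == 1))

  expect_error(synthetic_spec(substitution_prob = 1))

  spec <- synthetic_spec(seed = 50, n_species = 8, substitution_prob = 0.1)
  sim <- simulate_ortholog_peptides(spec, strrep("MKLVAGHTSW", 9))
  mut_rate <- mean(sim$truth$mutated_columns)
  expect_lt(abs(mut_rate - 0.1),
            3 * sqrt(0.1 * 0.9 / length(sim$truth$mutated_columns)))
  # truth record marks exactly the changed residues
  base <- strsplit(sim$truth$base_peptide, "")[[1]]
  changed <- t(vapply(strsplit(sim$peptides, ""),
                      function(x) x != base, logical(length(base))))
  expect_equal(unname(changed), sim$truth$mutated_columns)
})

test_that("invalid generator geometry is rejected", {
  expect_error(synthetic_spec(cds_len = 100))       # not a codon multiple
  expect_error(synthetic_spec(isr_len = 31))
  expect_error(synthetic_spec(readthrough_fraction = 1.2))
  expect_error(synthetic_spec(read_len_range = c(30, 24)))
  expect_error(synthetic_spec(n_replicates = 1))
})
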