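test_that("adapter trimming recovers exact cut points", {
  adapter <- "AGATCGGAAGAG"
  r <- footprint_reads("a", paste0("ACGTACGT", adapter))
  expect_equal(trim_adapter(r, adapter)$seq, "ACGTACGT")

  r2 <- footprint_reads("b", "ACGTACGTACGTACGTACGTACGT")
  expect_equal(trim_adapter(r2, adapter)$seq, r2$seq)

  # partial adapter prefix at the 3' end is removed when >= min_overlap
  r3 <- footprint_reads("c", paste0("CCCCCCCC", substr(adapter, 1, 7)))
  expect_equal(trim_adapter(r3, adapter, min_overlap = 6)$seq, "CCCCCCCC")
  expect_equal(trim_adapter(r3, adapter, min_overlap = 8)$seq, r3$seq)

  # 500 simulated reads with the adapter appended at known cut points
  set.seed(5)
  nt <- c("A", "C", "G", "T")
  insert_len <- sample(18:32, 500, replace = TRUE)
  inserts <- vapply(insert_len, function(n)
    paste(sample(nt, n, replace = TRUE), collapse = ""), character(1))
  # avoid inserts that already end in a long adapter prefix by construction:
  # use an adapter alphabet-distinct marker-free check via exact recovery
  contaminated <- paste0(inserts, adapter)
  trimmed <- trim_adapter(footprint_reads(sprintf("r%03d", 1:500), contaminated),
                          adapter, min_overlap = 6)
  ok <- trimmed$seq == inserts
  # a few inserts may legitimately end in an adapter prefix >= 6 nt; those
  # trim earlier, which the exact-string rule requires
  earlier <- nchar(trimmed$seq) < nchar(inserts)
  expect_true(all(ok | earlier))
  expect_gt(mean(ok), 0.95)
})

test_that("length/N filtering keeps the inclusive boundary and tallies removals", {
  r <- footprint_reads(c("a", "b", "c"),
                       c(strrep("A", 23), strrep("C", 24), strrep("G", 25)))
  flt <- filter_reads(r, min_len = 24)
  expect_equal(flt$reads$length, c(24L, 25L))
  expect_equal(flt$n_filtered, 1L)

  rn <- footprint_reads("n", paste0(strrep("A", 20), "N", strrep("A", 10)))
  expect_equal(filter_reads(rn)$n_filtered, 1L)

  set.seed(6)
  lens <- sample(18:36, 10000, replace = TRUE)
  seqs <- vapply(lens, function(n)
    paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = ""),
    character(1))
  flt2 <- filter_reads(footprint_reads(sprintf("r%05d", 1:10000), seqs))
  expect_equal(nrow(flt2$reads), sum(lens >= 24))
})

test_that("exact mapping places unique reads and flags repeats and mismatches", {
  set.seed(8)
  t <- random_transcript(utr5 = 10, cds_codons = 30, utr3 = 120)
  read <- substr(t$seq, 11, 40)
  m <- map_exact(read, t)
  expect_equal(m$status, "mapped")
  expect_equal(m$position, 10L)

  # a repeated 30-mer makes the read ambiguous
  rep_seq <- paste0(strrep("A", 5), read, strrep("C", 4), read, "TGA")
  t2 <- transcript_model("rep", paste0("ATG", rep_seq),
                         0, 3 + nchar(rep_seq))
  # ensure CDS ends in TGA by construction
  expect_equal(map_exact(read, t2)$status, "ambiguous")

  # one mismatch violates the 100%-match rule
  bad <- read
  substr(bad, 15, 15) <- setdiff(c("A","C","G","T"), substr(read, 15, 15))[1]
  expect_equal(map_exact(bad, t)$status, "unmapped")
})

test_that("region scheme follows the window offsets and partitions the transcript", {
  # arithmetic from the stated offsets on toy coordinates
  a <- structure(list(transcript_id = "toy", stop1_start = 150L,
                      stop2_start = 300L, isr_start = 153L, isr_end = 300L,
                      isr_len_nt = 147L, extension_len_aa = 49L,
                      extension_peptide = NA_character_,
                      no_downstream_stop = FALSE, stop1_codon = "TGA"),
                 class = "isr_annotation")
  t <- structure(list(id = "toy", seq = strrep("A", 400), cds_start = 50L,
                      cds_end = 153L), class = "transcript_model")
  sch <- build_region_scheme(t, a, 12, 22)
  expect_equal(sch$start, c(0L, 50L, 138L, 278L))
  expect_equal(sch$end, c(50L, 138L, 278L, 400L))
  expect_equal(sum(sch$length), 400L)

  # offsets (0,0) give the ISR window [stop1_start, stop2_start)
  sch0 <- build_region_scheme(t, a, 0, 0)
  expect_equal(sch0$start[sch0$region == "isr_window"], 150L)
  expect_equal(sch0$end[sch0$region == "isr_window"], 300L)

  # an ISR too short for the offsets is a degenerate window
  spec <- synthetic_spec(seed = 31, isr_len = 18L)
  tx <- make_transcript(spec)
  expect_error(build_region_scheme(tx$transcript, tx$annotation, 12, 40),
               "degenerate")

  # partition invariant over random geometries
  set.seed(9)
  for (i in 1:50) {
    spec <- synthetic_spec(seed = 100 + i,
                           isr_len = 3L * sample(10:120, 1),
                           utr3_rest_len = sample(50:400, 1))
    tx <- make_transcript(spec)
    sch <- build_region_scheme(tx$transcript, tx$annotation)
    expect_equal(sch$start[-1], sch$end[-4])
    expect_equal(sum(sch$length), nchar(tx$transcript$seq))
  }
})

test_that("region assignment matches an interval-membership oracle", {
  sch <- fake_scheme(50L, 138L, 278L, 400L)
  # half-open boundaries
  expect_equal(assign_region(138L, sch), "isr_window")
  expect_equal(assign_region(278L, sch), "three_utr_rest")
  expect_equal(assign_region(0L, sch), "five_utr")
  set.seed(10)
  pos <- sample(0:399, 2000, replace = TRUE)
  expect_equal(assign_region(pos, sch), oracle_assign(pos, sch))
  # majority-overlap alternative agrees with a direct overlap argmax
  lens <- sample(24:34, 2000, replace = TRUE)
  pos2 <- sample(0:365, 2000, replace = TRUE)
  lab <- assign_region(pos2, sch, rule = "overlap", read_len = lens)
  direct <- vapply(seq_along(pos2), function(i) {
    ov <- pmax(0, pmin(sch$end, pos2[i] + lens[i]) - pmax(sch$start, pos2[i]))
    sch$region[which.max(ov)]
  }, character(1))
  expect_equal(lab, direct)
})

test_that("densities divide counts by region length with full accounting", {
  sch <- fake_scheme(50L, 150L, 250L, 400L)  # ISR window length 100
  tb <- compute_densities(rep("isr_window", 10), sch, "d1")
  expect_equal(tb$regions$density[tb$regions$region == "isr_window"], 0.10)

  tb0 <- compute_densities(character(0), sch, "empty")
  expect_equal(tb0$regions$read_count, rep(0L, 4))
  expect_equal(tb0$regions$density, rep(0, 4))

  tb2 <- compute_densities(c(rep("cds_body", 7), rep("five_utr", 2)), sch,
                           "d2", n_unmapped = 3, n_ambiguous = 1,
                           n_filtered = 4)
  expect_equal(tb2$n_total, 9L + 3L + 1L + 4L)
})

test_that("the full pipeline keeps the read-accounting invariant under contamination", {
  spec <- synthetic_spec(seed = 33, n_reads = 4000L)
  tx <- make_transcript(spec)
  adapter <- "AGATCGGAAGAGC"
  sim <- simulate_footprints(tx$transcript, tx$annotation, spec,
                             mismatch_rate = 0.05, adapter = adapter,
                             adapter_rate = 0.3)
  n_input <- nrow(sim$reads)
  tb <- region_density_pipeline(sim$reads, tx$transcript, tx$annotation,
                                dataset_id = "contaminated", adapter = adapter)
  expect_equal(tb$n_total, n_input)
  expect_equal(sum(tb$regions$read_count) + tb$n_unmapped + tb$n_ambiguous +
                 tb$n_filtered, n_input)
  # mismatched reads cannot map under the 100%-match rule
  expect_gte(tb$n_unmapped, 1L)
  # adapter-bearing reads were rescued by trimming: most reads still assign
  expect_gt(sum(tb$regions$read_count) / n_input, 0.85)
})

test_that("recovered region densities lie within sampling error of the truth", {
  # d = 0.05, r = 0.1, b = 5e-4, 50k reads; counts aggregated over 5
  # libraries so the 3-binomial-SE bound applies to the summed counts
  regions <- c("five_utr", "cds_body", "isr_window", "three_utr_rest")
  tx <- make_transcript(synthetic_spec(seed = 34))
  got <- expected <- setNames(numeric(4), regions)
  for (i in 1:5) {
    spec <- synthetic_spec(seed = 340L + i)
    sim <- simulate_footprints(tx$transcript, tx$annotation, spec)
    tb <- region_density_pipeline(sim$reads, tx$transcript, tx$annotation)
    got <- got + setNames(tb$regions$read_count, tb$regions$region)[regions]
    expected <- expected + unlist(sim$truth$expected_region_counts)[regions]
  }
  for (region in regions)
    expect_lt(abs(got[[region]] - expected[[region]]),
              3 * sqrt(expected[[region]]) + 1)
})

test_that("the cross-dataset comparison is a two-sided Welch test with ratios", {
  sch <- fake_scheme(50L, 150L, 250L, 400L)
  mk <- function(isr_n, utr_n, id) {
    compute_densities(c(rep("isr_window", isr_n), rep("three_utr_rest", utr_n)),
                      sch, id)
  }
  same <- lapply(1:4, function(i) mk(20, 30, paste0("s", i)))
  cmp <- compare_isr_vs_utr(same)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$per_dataset$ratio,
               rep((20 / 100) / (30 / 150), 4))
  expect_error(compare_isr_vs_utr(same[1]), "at least 2")

  set.seed(12)
  tabs <- lapply(1:15, function(i) mk(rpois(1, 200), rpois(1, 30),
                                      sprintf("d%02d", i)))
  cmp2 <- compare_isr_vs_utr(tabs)
  oracle <- oracle_welch(cmp2$per_dataset$isr_density,
                         cmp2$per_dataset$utr_density)
  expect_equal(cmp2$t_statistic, oracle$t, tolerance = 1e-12)
  expect_equal(cmp2$p_value, oracle$p, tolerance = 1e-12)
})

test_that("FASTQ round-trips through the reader and writer", {
  spec <- synthetic_spec(seed = 35, n_reads = 200L)
  tx <- make_transcript(spec)
  sim <- simulate_footprints(tx$transcript, tx$annotation, spec)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  back <- read_fastq(fq)
  expect_equal(back$seq, sim$reads$seq)
  expect_equal(back$id, sim$reads$id)
})
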