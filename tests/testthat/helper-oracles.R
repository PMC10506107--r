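# Independent brute-force oracles and small random-instance generators.
# These deliberately avoid the code paths they check.

# first in-frame stop at/after `from` (0-based), scanning every triplet
oracle_scan_stop2 <- function(seq, from) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  p <- from
  while (p + 3L <= n) {
    if (substr(seq, p + 1L, p + 3L) %in% stops) return(p)
    p <- p + 3L
  }
  NA_integer_
}

# interval membership by explicit loop over scheme rows
oracle_assign <- function(position, scheme) {
  vapply(position, function(p) {
    for (i in seq_len(nrow(scheme))) {
      if (p >= scheme$start[i] && p < scheme$end[i]) return(scheme$region[i])
    }
    NA_character_
  }, character(1))
}

# textbook Welch statistic, Welch-Satterthwaite df, two-sided p
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# per-column identity tally over a character matrix of residues
oracle_column_identity <- function(peptides) {
  mat <- do.call(rbind, strsplit(peptides, ""))
  apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    max(table(col)) / length(col)
  })
}

# random valid transcript: random sequence with a stop codon planted at
# the CDS end (internal CDS stops are irrelevant to the downstream scan)
random_transcript <- function(id = "rnd", utr5 = sample(0:30, 1),
                              cds_codons = sample(10:40, 1),
                              utr3 = sample(0:400, 1)) {
  nt <- c("A", "C", "G", "T")
  n <- utr5 + 3 * cds_codons + utr3
  seq <- paste(sample(nt, n, replace = TRUE), collapse = "")
  cds_end <- utr5 + 3 * cds_codons
  substr(seq, cds_end - 2L, cds_end) <- sample(c("TAA", "TAG", "TGA"), 1)
  transcript_model(id, seq, utr5, cds_end)
}

# fabricate a region scheme directly from boundary coordinates (bypasses
# build_region_scheme so its arithmetic can be tested independently)
fake_scheme <- function(cds_start, w_start, w_end, n) {
  df <- data.frame(
    region = c("five_utr", "cds_body", "isr_window", "three_utr_rest"),
    start = c(0L, cds_start, w_start, w_end),
    end = c(cds_start, w_start, w_end, n),
    stringsAsFactors = FALSE
  )
  df$length <- df$end - df$start
  structure(df, class = c("region_scheme", "data.frame"),
            transcript_id = "fake", transcript_length = n,
            upstream_offset = NA_integer_, downstream_offset = NA_integer_)
}

fixture <- function(name) system.file("extdata", name, package = "tcrkit")
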