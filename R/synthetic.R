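# Synthetic-data generators. They emulate the statistical structure the
# analysis assumes — transcript architecture with exactly one downstream
# in-frame stop, footprint libraries with region-specific per-nucleotide
# intensities, luciferase replicates with multiplicative noise, and
# ortholog peptide panels — so every pipeline stage is testable with no
# external download. All generators are deterministic under (seed, spec)
# and return a machine-readable truth record beside the fixture.

SENSE_CODONS <- setdiff(
  as.vector(outer(outer(c("T","C","A","G"), c("T","C","A","G"), paste0),
                  c("T","C","A","G"), paste0)),
  c("TAA", "TAG", "TGA"))

AA_RESIDUES <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V")

#' Parameters for the synthetic-data generators
#'
#' Defaults describe a neuronatin-like transcript (81-aa CDS, 267-nt ISR)
#' and footprint libraries with a strong CDS signal, a small readthrough
#' signal over the ISR, and a low uniform background — densities are
#' relative intensities; the library is scaled to `n_reads` expected reads.
#'
#' @param seed Integer seed; every generator call is deterministic under it.
#' @param utr5_len,cds_len,isr_len,utr3_rest_len Transcript geometry in nt.
#'   `cds_len` includes the canonical stop codon; `cds_len` and `isr_len`
#'   must be divisible by 3.
#' @param cds_density CDS footprint intensity `d` (reads/nt).
#' @param readthrough_fraction Readthrough fraction `r` in `[0, 1]`; the
#'   ISR-window intensity is `background_density + r * cds_density`.
#' @param background_density Uniform background intensity `b` (reads/nt).
#' @param read_len_range Footprint length range in nt, inclusive.
#' @param n_reads Expected library size; `NULL` leaves intensities unscaled.
#' @param true_percent True readthrough efficiency of the luciferase model
#'   (percent scale).
#' @param noise_sigma Log-scale SD of the multiplicative luciferase noise.
#' @param n_replicates Luciferase replicates per construct (>= 2).
#' @param base_ratio Median no-stop FLuc/RLuc ratio.
#' @param n_species Ortholog panel size.
#' @param substitution_prob Per-column substitution probability in `[0, 1)`.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           utr5_len = 90L, cds_len = 246L, isr_len = 267L,
                           utr3_rest_len = 300L,
                           cds_density = 0.05, readthrough_fraction = 0.1,
                           background_density = 5e-4,
                           read_len_range = c(24L, 34L), n_reads = 50000L,
                           true_percent = 11.1, noise_sigma = 0.2,
                           n_replicates = 6L, base_ratio = 0.63,
                           n_species = 8L, substitution_prob = 0.1) {
  spec <- list(seed = as.integer(seed),
               utr5_len = as.integer(utr5_len),
               cds_len = as.integer(cds_len),
               isr_len = as.integer(isr_len),
               utr3_rest_len = as.integer(utr3_rest_len),
               cds_density = cds_density,
               readthrough_fraction = readthrough_fraction,
               background_density = background_density,
               read_len_range = as.integer(read_len_range),
               n_reads = if (is.null(n_reads)) NULL else as.integer(n_reads),
               true_percent = true_percent,
               noise_sigma = noise_sigma,
               n_replicates = as.integer(n_replicates),
               base_ratio = base_ratio,
               n_species = as.integer(n_species),
               substitution_prob = substitution_prob)
  with(spec, {
    stopifnot(utr5_len > 0L, cds_len > 0L, isr_len >= 0L, utr3_rest_len > 0L,
              cds_len %% 3L == 0L, isr_len %% 3L == 0L,
              readthrough_fraction >= 0, readthrough_fraction <= 1,
              cds_density >= 0, background_density >= 0,
              length(read_len_range) == 2L, read_len_range[1L] >= 1L,
              read_len_range[1L] <= read_len_range[2L],
              is.null(n_reads) || n_reads >= 0L,
              true_percent >= 0, noise_sigma >= 0, n_replicates >= 2L,
              base_ratio > 0, n_species >= 2L,
              substitution_prob >= 0, substitution_prob < 1)
  })
  structure(spec, class = "synthetic_spec")
}

#' Generate a transcript with a planted downstream in-frame stop
#'
#' Layout: 5'UTR | CDS (sense codons + one canonical stop) | ISR (sense
#' codons only) | planted stop 2 | distal 3'UTR. The CDS and ISR are
#' rejection-free by construction (codons drawn from the 61 sense codons),
#' so the planted stop is the first in-frame stop downstream of the
#' canonical one.
#'
#' @param spec A [synthetic_spec()].
#' @param stop1 Canonical stop codon (default `"TGA"`, the readthrough-
#'   permissive stop).
#' @return A list with `transcript` (a [transcript_model]) and
#'   `annotation` (its `isr_annotation`, which recovers the planted stop).
#' @export
make_transcript <- function(spec, stop1 = "TGA") {
  stopifnot(inherits(spec, "synthetic_spec"), stop1 %in% STOP_CODONS)
  set.seed(spec$seed)
  nt <- c("A", "C", "G", "T")
  utr5 <- paste(sample(nt, spec$utr5_len, replace = TRUE), collapse = "")
  n_sense <- spec$cds_len %/% 3L - 1L
  cds <- paste0(paste(sample(SENSE_CODONS, n_sense, replace = TRUE),
                      collapse = ""), stop1)
  isr <- paste(sample(SENSE_CODONS, spec$isr_len %/% 3L, replace = TRUE),
               collapse = "")
  stop2 <- sample(STOP_CODONS, 1L)
  utr3 <- paste(sample(nt, spec$utr3_rest_len, replace = TRUE), collapse = "")
  t <- transcript_model(
    id = sprintf("synth_tx_seed%d", spec$seed),
    seq = paste0(utr5, cds, isr, stop2, utr3),
    cds_start = spec$utr5_len,
    cds_end = spec$utr5_len + spec$cds_len
  )
  a <- find_downstream_inframe_stop(t)
  # the planted stop must be the one recovered
  stopifnot(a$stop2_start == t$cds_end + spec$isr_len)
  list(transcript = t, annotation = a)
}

# Region intensities (reads/nt) of the piecewise-constant footprint model.
region_intensity <- function(spec) {
  c(five_utr = spec$background_density,
    cds_body = spec$cds_density,
    isr_window = spec$background_density +
      spec$readthrough_fraction * spec$cds_density,
    three_utr_rest = spec$background_density)
}

# Per-position Poisson intensity of 5'-end placements over the eligible
# positions [0, len - min_read_len], from the piecewise-constant region
# model; scaled so that the expected library size equals n_reads.
footprint_lambda <- function(transcript, annotation, spec,
                             upstream_offset = 12L, downstream_offset = 22L) {
  scheme <- build_region_scheme(transcript, annotation,
                                upstream_offset, downstream_offset)
  n <- nchar(transcript$seq)
  max_pos <- n - spec$read_len_range[1L]
  pos <- 0:max_pos
  labels <- assign_region(pos, scheme)
  lambda <- unname(region_intensity(spec)[labels])
  if (!is.null(spec$n_reads) && sum(lambda) > 0)
    lambda <- lambda * spec$n_reads / sum(lambda)
  list(pos = pos, lambda = lambda, labels = labels, scheme = scheme)
}

#' Simulate a ribosome-footprint library
#'
#' Read 5'-end positions are drawn from a piecewise-constant Poisson
#' intensity: `cds_density` on the CDS body, `background + r * cds_density`
#' on the ISR window, and `background` on the 5'UTR and distal 3'UTR.
#' Lengths are uniform over `read_len_range` (clipped at the transcript
#' end) and sequences are copied exactly from the transcript, so every
#' clean read maps with 100% identity by construction. Optional
#' contamination introduces single mismatches (unmappable under the exact
#' rule) or appends the adapter (recoverable by [trim_adapter()]).
#'
#' @param transcript,annotation Output of [make_transcript()] (or any
#'   transcript/annotation pair).
#' @param spec A [synthetic_spec()].
#' @param upstream_offset,downstream_offset ISR window offsets the
#'   intensity model uses (defaults 12, 22; keep equal to the analysis
#'   offsets so recovery is well-posed).
#' @param mismatch_rate Fraction of reads given one random mismatch.
#' @param adapter Optional adapter appended to `adapter_rate` of the reads.
#' @param adapter_rate Fraction of reads with the adapter appended.
#' @return A list with `reads` (a `footprint_reads` data.frame) and
#'   `truth` (parameters, the region scheme, per-region expected counts
#'   and densities, and per-read true positions).
#' @export
simulate_footprints <- function(transcript, annotation, spec,
                                upstream_offset = 12L, downstream_offset = 22L,
                                mismatch_rate = 0, adapter = NULL,
                                adapter_rate = 0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  mod <- footprint_lambda(transcript, annotation, spec,
                          upstream_offset, downstream_offset)
  counts <- stats::rpois(length(mod$lambda), mod$lambda)
  pos <- rep(mod$pos, counts)
  n_reads <- length(pos)
  n <- nchar(transcript$seq)
  len <- sample(seq(spec$read_len_range[1L], spec$read_len_range[2L]),
                n_reads, replace = TRUE)
  len <- pmin(len, n - pos)
  seqs <- substring(transcript$seq, pos + 1L, pos + len)
  if (mismatch_rate > 0 && n_reads > 0) {
    hit <- which(stats::runif(n_reads) < mismatch_rate)
    for (i in hit) {
      j <- sample.int(len[i], 1L)
      old <- substr(seqs[i], j, j)
      substr(seqs[i], j, j) <- sample(setdiff(c("A","C","G","T"), old), 1L)
    }
  } else hit <- integer(0)
  if (!is.null(adapter) && adapter_rate > 0 && n_reads > 0) {
    ad <- which(stats::runif(n_reads) < adapter_rate)
    seqs[ad] <- paste0(seqs[ad], adapter)
  } else ad <- integer(0)
  expected <- tapply(mod$lambda, factor(mod$labels, levels = REGION_LEVELS),
                     sum, default = 0)
  truth <- list(
    spec = unclass(spec),
    scheme = mod$scheme,
    expected_region_counts = as.list(expected),
    expected_density = as.list(expected / mod$scheme$length),
    n_reads = n_reads,
    positions = pos,
    n_mismatched = length(hit),
    n_with_adapter = length(ad)
  )
  reads <- footprint_reads(sprintf("fp%06d", seq_len(max(n_reads, 0L))), seqs)
  list(reads = reads, truth = truth)
}

#' Simulate per-region footprint counts directly
#'
#' Count-level sampler for the piecewise-constant intensity model of
#' [simulate_footprints()]: a region's read count is the sum of
#' independent per-nucleotide Poisson counts, so one Poisson draw per
#' region with mean `intensity * region length` (scaled to `n_reads`
#' expected reads per library) has exactly the region-count distribution
#' the intensity model defines. Because it is free of read-placement edge
#' effects (a read must fit on the transcript, so the read-level
#' generator cannot place 5' ends on the last few nucleotides), this is
#' the appropriate sampler for calibration studies over many replicate
#' libraries where read sequences are never needed.
#'
#' @inheritParams simulate_footprints
#' @param n_datasets Number of replicate libraries to draw.
#' @return A list of `region_density_table` objects of length `n_datasets`.
#' @export
simulate_region_counts <- function(transcript, annotation, spec,
                                   n_datasets = 1L,
                                   upstream_offset = 12L,
                                   downstream_offset = 22L) {
  stopifnot(inherits(spec, "synthetic_spec"), n_datasets >= 1L)
  set.seed(spec$seed)
  scheme <- build_region_scheme(transcript, annotation,
                                upstream_offset, downstream_offset)
  lam <- region_intensity(spec)[scheme$region] * scheme$length
  if (!is.null(spec$n_reads) && sum(lam) > 0)
    lam <- lam * spec$n_reads / sum(lam)
  lapply(seq_len(n_datasets), function(i) {
    counts <- stats::rpois(length(REGION_LEVELS), as.numeric(lam))
    labels <- rep(scheme$region, counts)
    compute_densities(labels, scheme,
                      dataset_id = sprintf("sim%03d", i))
  })
}

#' Simulate a dual-luciferase table
#'
#' No-stop ratios are log-normal around `base_ratio`; with-stop ratios are
#' log-normal around `base_ratio * true_percent/100`; per-replicate RLuc
#' values are drawn log-normally and FLuc is reconstructed as
#' `ratio * rluc`, so row-wise ratios carry the intended structure.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `table` (a `luciferase_table` with constructs
#'   `with_stop` and `no_stop`) and `truth`.
#' @export
simulate_luciferase <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_replicates
  pi_frac <- spec$true_percent / 100
  ratio_no <- spec$base_ratio * exp(stats::rnorm(n, 0, spec$noise_sigma))
  ratio_with <- spec$base_ratio * pi_frac *
    exp(stats::rnorm(n, 0, spec$noise_sigma))
  rluc <- exp(stats::rnorm(2L * n, log(1e5), 0.1))
  df <- data.frame(
    construct = rep(c("with_stop", "no_stop"), each = n),
    replicate = rep(sprintf("R%d", seq_len(n)), 2L),
    rluc = rluc,
    stringsAsFactors = FALSE
  )
  df$fluc <- c(ratio_with, ratio_no) * df$rluc
  truth <- list(true_percent = spec$true_percent,
                base_ratio = spec$base_ratio,
                noise_sigma = spec$noise_sigma,
                n_replicates = n)
  list(table = luciferase_table(df[, c("construct", "replicate",
                                       "fluc", "rluc")]),
       truth = truth)
}

#' Simulate an ortholog extension-peptide panel
#'
#' Each species copies the base peptide with i.i.d. per-column
#' substitution (probability `substitution_prob`) to a uniformly chosen
#' different residue.
#'
#' @param spec A [synthetic_spec()].
#' @param base_peptide Ancestral amino-acid string.
#' @return A list with `peptides` (named character vector, one per
#'   species) and `truth` (logical matrix of mutated columns).
#' @export
simulate_ortholog_peptides <- function(spec, base_peptide) {
  stopifnot(inherits(spec, "synthetic_spec"),
            is.character(base_peptide), nzchar(base_peptide))
  set.seed(spec$seed)
  base <- strsplit(toupper(base_peptide), "")[[1L]]
  L <- length(base)
  mutated <- matrix(FALSE, spec$n_species, L)
  peptides <- character(spec$n_species)
  for (s in seq_len(spec$n_species)) {
    res <- base
    mut <- stats::runif(L) < spec$substitution_prob
    for (j in which(mut))
      res[j] <- sample(setdiff(AA_RESIDUES, res[j]), 1L)
    mutated[s, ] <- mut
    peptides[s] <- paste(res, collapse = "")
  }
  names(peptides) <- sprintf("species%02d", seq_len(spec$n_species))
  list(peptides = peptides,
       truth = list(base_peptide = base_peptide, mutated_columns = mutated,
                    substitution_prob = spec$substitution_prob))
}

#' Write named sequences to FASTA
#' @param seqs Named character vector (nucleotide or amino-acid strings).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
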