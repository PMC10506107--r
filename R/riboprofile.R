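# Ribosome-footprint region-density analysis: adapter trimming, length/N
# filtering, exact (100% match) mapping to a single reference transcript,
# region assignment with the ISR window offsets, per-nucleotide densities,
# and the cross-dataset ISR-vs-3'UTR comparison.

REGION_LEVELS <- c("five_utr", "cds_body", "isr_window", "three_utr_rest")

#' Construct a footprint read table
#'
#' @param id Character vector of read identifiers.
#' @param seq Character vector of read sequences over `{A,C,G,T,N}`.
#' @return A data.frame of class `footprint_reads` with columns
#'   `id`, `seq`, `length`.
#' @export
footprint_reads <- function(id, seq) {
  stopifnot(length(id) == length(seq))
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad))
    stop("read(s) with characters outside {A,C,G,T,N}: ",
         paste(head(id[bad], 3L), collapse = ", "))
  structure(
    data.frame(id = as.character(id), seq = seq, length = nchar(seq),
               stringsAsFactors = FALSE),
    class = c("footprint_reads", "data.frame")
  )
}

#' Read footprint reads from a FASTQ file
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return A `footprint_reads` data.frame.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  footprint_reads(sub("\\s.*$", "", names(x)), as.character(x))
}

#' Write footprint reads to FASTQ
#' @param reads A `footprint_reads` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  quals <- Biostrings::PhredQuality(vapply(reads$length, function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

trim_point <- function(s, adapter, min_overlap) {
  n <- nchar(s)
  la <- nchar(adapter)
  # leftmost position where a prefix of the adapter (>= min_overlap nt,
  # exact) either runs to the read's 3' end or is the full adapter
  for (p in seq_len(n)) {
    k <- min(la, n - p + 1L)
    if (k < min_overlap) break
    if (substr(s, p, p + k - 1L) == substr(adapter, 1L, k) &&
        (k == la || p + k - 1L == n))
      return(p)
  }
  n + 1L
}

#' Trim a 3' adapter by exact prefix match
#'
#' Minimal exact-match trimmer: the read is truncated at the leftmost
#' position where a prefix of the adapter of at least `min_overlap`
#' nucleotides matches exactly and either extends to the read's 3' end or
#' is the complete adapter. Reads without such a match are returned
#' unchanged. Pre-trimmed FASTQ input is the documented default path;
#' this trimmer covers simulated contamination and simple libraries.
#'
#' @param reads A `footprint_reads` data.frame.
#' @param adapter Non-empty adapter sequence.
#' @param min_overlap Minimum exact overlap in nt (default 6).
#' @return A `footprint_reads` data.frame with trimmed sequences.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L) {
  stopifnot(inherits(reads, "footprint_reads"),
            is.character(adapter), nzchar(adapter), min_overlap >= 1L)
  adapter <- normalize_nt(adapter)
  cut <- vapply(reads$seq, trim_point, integer(1),
                adapter = adapter, min_overlap = as.integer(min_overlap),
                USE.NAMES = FALSE)
  footprint_reads(reads$id, substr(reads$seq, 1L, cut - 1L))
}

#' Filter footprint reads by length and ambiguous bases
#'
#' Retains reads of at least `min_len` nucleotides containing no `N`
#' (the 100%-match mapping rule makes `N`-containing reads unmappable).
#'
#' @param reads A `footprint_reads` data.frame.
#' @param min_len Minimum read length in nt (default 24).
#' @return A list with `reads` (the retained `footprint_reads`),
#'   `n_filtered` (total removed), `n_short`, and `n_with_n`.
#' @export
filter_reads <- function(reads, min_len = 24L) {
  stopifnot(inherits(reads, "footprint_reads"), min_len >= 1L)
  short <- reads$length < min_len
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  keep <- !short & !has_n
  list(reads = footprint_reads(reads$id[keep], reads$seq[keep]),
       n_filtered = sum(!keep),
       n_short = sum(short),
       n_with_n = sum(has_n & !short))
}

#' Map reads to a transcript by exact match
#'
#' Exact substring search on the sense strand (100% match). A read with
#' exactly one occurrence is placed at its 0-based start position; zero
#' occurrences is `unmapped`; two or more is `ambiguous` (excluded from
#' densities, counted separately). With `strand = "both"` a read absent
#' from the sense strand is additionally searched as its reverse
#' complement.
#'
#' @param reads A `footprint_reads` data.frame.
#' @param transcript A [transcript_model].
#' @param strand `"sense"` (default) or `"both"`.
#' @return `reads` with added columns `position` (0-based, `NA` when not
#'   uniquely placed) and `status` (`mapped` / `unmapped` / `ambiguous`).
#' @export
map_reads <- function(reads, transcript, strand = c("sense", "both")) {
  strand <- match.arg(strand)
  stopifnot(inherits(reads, "footprint_reads"),
            inherits(transcript, "transcript_model"))
  s <- transcript$seq
  n <- nchar(s)
  position <- rep(NA_integer_, nrow(reads))
  status <- rep("unmapped", nrow(reads))
  query <- reads$seq
  if (strand == "both" && nrow(reads)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(query)))
    on_sense <- vapply(seq_along(query), function(i)
      grepl(query[i], s, fixed = TRUE), logical(1))
    query <- ifelse(on_sense, query, rc)
  }
  for (L in unique(reads$length)) {
    if (L < 1L || L > n) next
    idx <- which(reads$length == L)
    windows <- substring(s, 1:(n - L + 1L), L:n)
    occ <- table(windows)
    hits <- match(query[idx], windows)
    counts <- as.integer(occ[query[idx]])
    counts[is.na(counts)] <- 0L
    status[idx[counts == 1L]] <- "mapped"
    status[idx[counts >= 2L]] <- "ambiguous"
    position[idx[counts == 1L]] <- hits[counts == 1L] - 1L
  }
  reads$position <- position
  reads$status <- status
  reads
}

#' Map a single read
#' @inheritParams map_reads
#' @param read A one-row `footprint_reads` (or a plain sequence string).
#' @return A list with `status` and `position` (0-based or `NA`).
#' @export
map_exact <- function(read, transcript, strand = c("sense", "both")) {
  if (is.character(read)) read <- footprint_reads("read", read)
  m <- map_reads(read, transcript, strand = match.arg(strand))
  list(status = m$status[1L], position = m$position[1L])
}

#' Build the four-region transcript partition
#'
#' Partitions the transcript into 5'UTR, CDS body, ISR window, and distal
#' 3'UTR using the ISR window offsets: the ISR window runs from
#' `upstream_offset` nt upstream of the first nucleotide of the canonical
#' stop codon to `downstream_offset` nt upstream of the downstream in-frame
#' stop codon. With the default offsets (12, 22) the window is a P-site
#' proxy for footprints assigned by their 5' end.
#'
#' @param t A [transcript_model].
#' @param a An `isr_annotation` with an ISR present.
#' @param upstream_offset Window extension upstream of stop 1, nt (default 12).
#' @param downstream_offset Window truncation upstream of stop 2, nt (default 22).
#' @return An object of class `region_scheme`: a data.frame of 0-based
#'   half-open intervals (`region`, `start`, `end`, `length`) plus the
#'   offsets and the transcript length as attributes.
#' @export
build_region_scheme <- function(t, a, upstream_offset = 12L,
                                downstream_offset = 22L) {
  stopifnot(inherits(t, "transcript_model"), inherits(a, "isr_annotation"))
  if (isTRUE(a$no_downstream_stop))
    stop("transcript '", t$id, "': no ISR; cannot build a region scheme")
  up <- as.integer(upstream_offset)
  down <- as.integer(downstream_offset)
  stopifnot(up >= 0L, down >= 0L)
  n <- nchar(t$seq)
  w_start <- a$stop1_start - up
  w_end <- a$stop2_start - down
  if (w_start <= t$cds_start)
    stop("transcript '", t$id, "': upstream offset ", up,
         " reaches past the CDS start")
  if (w_start >= w_end)
    stop("transcript '", t$id, "': degenerate ISR window; with offsets (",
         up, ", ", down, ") the ISR must be at least ", down - up - 2L,
         " nt (it is ", a$isr_len_nt, " nt)")
  df <- data.frame(
    region = REGION_LEVELS,
    start = c(0L, t$cds_start, w_start, w_end),
    end = c(t$cds_start, w_start, w_end, n),
    stringsAsFactors = FALSE
  )
  df$length <- df$end - df$start
  structure(df,
            class = c("region_scheme", "data.frame"),
            transcript_id = t$id, transcript_length = n,
            upstream_offset = up, downstream_offset = down)
}

#' Assign mapped read positions to regions
#'
#' Default rule (`"five_prime"`): a read belongs to the region containing
#' its 5'-end position. The alternative `"overlap"` rule assigns the
#' region with the largest overlap with the read interval (ties to the
#' more 5' region) and requires `read_len`.
#'
#' @param position Integer vector of 0-based 5'-end positions.
#' @param scheme A `region_scheme`.
#' @param rule `"five_prime"` (default) or `"overlap"`.
#' @param read_len Read lengths (required for `rule = "overlap"`).
#' @return Character vector of region labels.
#' @export
assign_region <- function(position, scheme, rule = c("five_prime", "overlap"),
                          read_len = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(scheme, "region_scheme"))
  n <- attr(scheme, "transcript_length")
  if (any(position < 0L | position >= n))
    stop("position(s) outside the transcript [0, ", n, ")")
  if (rule == "five_prime") {
    breaks <- c(scheme$start, n)
    idx <- findInterval(position, breaks)
    # empty leading regions share a break; findInterval returns the
    # rightmost, i.e. the non-empty region containing the position
    return(scheme$region[pmin(idx, nrow(scheme))])
  }
  if (is.null(read_len))
    stop("rule = 'overlap' requires read_len")
  stopifnot(length(read_len) == length(position))
  ends <- pmin(position + read_len, n)
  vapply(seq_along(position), function(i) {
    ov <- pmax(0L, pmin(scheme$end, ends[i]) - pmax(scheme$start, position[i]))
    scheme$region[which.max(ov)]
  }, character(1))
}

#' Tabulate per-region read counts and densities
#'
#' Density is the region read count divided by the region length in
#' nucleotides (reads/nt). Unmapped, ambiguous, and filtered reads are
#' carried so that the accounting invariant
#' `sum(region counts) + n_unmapped + n_ambiguous + n_filtered = n_total`
#' holds for every run.
#'
#' @param labels Character vector of region labels for assigned reads.
#' @param scheme A `region_scheme`.
#' @param dataset_id Identifier for the footprint library.
#' @param n_unmapped,n_ambiguous,n_filtered Accounting counts (default 0).
#' @return An object of class `region_density_table`.
#' @export
compute_densities <- function(labels, scheme, dataset_id = "dataset",
                              n_unmapped = 0L, n_ambiguous = 0L,
                              n_filtered = 0L) {
  stopifnot(inherits(scheme, "region_scheme"))
  bad <- setdiff(unique(labels), REGION_LEVELS)
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  counts <- as.integer(table(factor(labels, levels = REGION_LEVELS)))
  regions <- data.frame(
    region = REGION_LEVELS,
    read_count = counts,
    region_len = scheme$length,
    stringsAsFactors = FALSE
  )
  regions$density <- ifelse(regions$region_len > 0,
                            regions$read_count / regions$region_len, NA_real_)
  structure(
    list(dataset_id = dataset_id,
         regions = regions,
         n_unmapped = as.integer(n_unmapped),
         n_ambiguous = as.integer(n_ambiguous),
         n_filtered = as.integer(n_filtered),
         n_total = sum(counts) + as.integer(n_unmapped) +
           as.integer(n_ambiguous) + as.integer(n_filtered)),
    class = "region_density_table"
  )
}

#' @export
print.region_density_table <- function(x, ...) {
  cat("<region_density_table> ", x$dataset_id, " (", x$n_total,
      " reads: ", sum(x$regions$read_count), " assigned, ", x$n_unmapped,
      " unmapped, ", x$n_ambiguous, " ambiguous, ", x$n_filtered,
      " filtered)\n", sep = "")
  print(x$regions, row.names = FALSE)
  invisible(x)
}

region_density <- function(table, region) {
  table$regions$density[match(region, table$regions$region)]
}

#' Write a region density table to TSV
#' @param table A `region_density_table`.
#' @param path Output path.
#' @return The written data.frame, invisibly.
#' @export
write_density_table <- function(table, path) {
  df <- table$regions
  df <- cbind(dataset_id = table$dataset_id, df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unmapped=%d ambiguous=%d filtered=%d total=%d",
                     table$n_unmapped, table$n_ambiguous, table$n_filtered,
                     table$n_total), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a region density table written by [write_density_table()]
#' @param path Path to the TSV.
#' @return A `region_density_table`.
#' @export
read_density_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  acc <- as.integer(regmatches(hdr, gregexpr("[0-9]+", hdr))[[1L]])
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(
    list(dataset_id = df$dataset_id[1L],
         regions = df[, c("region", "read_count", "region_len", "density")],
         n_unmapped = acc[1L], n_ambiguous = acc[2L], n_filtered = acc[3L],
         n_total = acc[4L]),
    class = "region_density_table"
  )
}

#' Run the footprint pipeline for one library
#'
#' Trims (optional), filters, maps, assigns, and tabulates a footprint
#' library against one transcript, with full read accounting.
#'
#' @param reads A `footprint_reads` data.frame (e.g. from [read_fastq()]).
#' @param transcript A [transcript_model].
#' @param annotation Optional `isr_annotation`; computed with
#'   [find_downstream_inframe_stop()] when `NULL`.
#' @param dataset_id Library identifier.
#' @param adapter Optional 3' adapter to trim before filtering.
#' @param min_overlap Minimum adapter overlap (see [trim_adapter()]).
#' @param min_len Minimum read length (default 24).
#' @param upstream_offset,downstream_offset ISR window offsets (12, 22).
#' @param strand Mapping strand mode (see [map_reads()]).
#' @param rule Region-assignment rule (see [assign_region()]).
#' @return A `region_density_table`; the per-stage counts are attached as
#'   attribute `"log"`.
#' @export
region_density_pipeline <- function(reads, transcript, annotation = NULL,
                                    dataset_id = "dataset", adapter = NULL,
                                    min_overlap = 6L, min_len = 24L,
                                    upstream_offset = 12L,
                                    downstream_offset = 22L,
                                    strand = "sense", rule = "five_prime") {
  if (is.null(annotation))
    annotation <- find_downstream_inframe_stop(transcript)
  n_input <- nrow(reads)
  if (!is.null(adapter))
    reads <- trim_adapter(reads, adapter, min_overlap)
  flt <- filter_reads(reads, min_len = min_len)
  mapped <- map_reads(flt$reads, transcript, strand = strand)
  scheme <- build_region_scheme(transcript, annotation,
                                upstream_offset, downstream_offset)
  is_mapped <- mapped$status == "mapped"
  labels <- assign_region(mapped$position[is_mapped], scheme, rule = rule,
                          read_len = mapped$length[is_mapped])
  out <- compute_densities(labels, scheme, dataset_id = dataset_id,
                           n_unmapped = sum(mapped$status == "unmapped"),
                           n_ambiguous = sum(mapped$status == "ambiguous"),
                           n_filtered = flt$n_filtered)
  stopifnot(out$n_total == n_input)  # accounting invariant
  attr(out, "log") <- list(n_input = n_input, n_filtered = flt$n_filtered,
                           n_short = flt$n_short, n_with_n = flt$n_with_n,
                           n_unmapped = out$n_unmapped,
                           n_ambiguous = out$n_ambiguous,
                           n_assigned = sum(out$regions$read_count))
  out
}

#' Compare ISR and distal-3'UTR densities across libraries
#'
#' Two-sided t-test with Welch's correction (unpaired by default) between
#' the per-library ISR-window densities and distal-3'UTR densities, plus
#' the per-library density ratio.
#'
#' @param tables List of >= 2 `region_density_table` objects.
#' @param paired Treat libraries as paired samples (default `FALSE`,
#'   matching independent public datasets).
#' @return A list of class `density_comparison`: `per_dataset` (data.frame
#'   with `dataset_id`, `isr_density`, `utr_density`, `ratio`),
#'   `t_statistic`, `df`, `p_value`, `n_datasets`.
#' @export
compare_isr_vs_utr <- function(tables, paired = FALSE) {
  if (length(tables) < 2L)
    stop("at least 2 datasets are required for the density comparison")
  per <- do.call(rbind, lapply(tables, function(tb) {
    data.frame(dataset_id = tb$dataset_id,
               isr_density = region_density(tb, "isr_window"),
               utr_density = region_density(tb, "three_utr_rest"),
               stringsAsFactors = FALSE)
  }))
  per$ratio <- per$isr_density / per$utr_density
  tt <- welch_ttest(per$isr_density, per$utr_density, paired = paired)
  structure(
    list(per_dataset = per, t_statistic = tt$t, df = tt$df,
         p_value = tt$p, n_datasets = nrow(per), paired = paired),
    class = "density_comparison"
  )
}

#' @export
print.density_comparison <- function(x, ...) {
  cat("<density_comparison> ", x$n_datasets, " datasets, ",
      if (x$paired) "paired" else "unpaired (Welch)", "\n", sep = "")
  cat(sprintf("  mean ISR density %.4g vs mean 3'UTR density %.4g reads/nt\n",
              mean(x$per_dataset$isr_density),
              mean(x$per_dataset$utr_density)))
  cat(sprintf("  t = %.3f, df = %.2f, p = %.3g\n", x$t_statistic, x$df,
              x$p_value))
  invisible(x)
}
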