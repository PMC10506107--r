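#' @importFrom utils read.delim write.table head
NULL

# The three canonical stop codons (DNA alphabet).
STOP_CODONS <- c("TAA", "TAG", "TGA")

normalize_nt <- function(seq) {
  seq <- toupper(seq)
  gsub("U", "T", seq, fixed = TRUE)
}

#' Build a transcript model
#'
#' A transcript model bundles a transcript sequence with its CDS
#' coordinates and is the source of all region geometry downstream.
#' Coordinates are 0-based, half-open: `cds_start` indexes the first
#' nucleotide of the start codon and `cds_end` is one past the last
#' nucleotide of the canonical stop codon ("stop 1").
#'
#' @param id Transcript identifier.
#' @param seq Nucleotide sequence over `{A,C,G,T}`; `U` is accepted on
#'   input and normalised to `T`.
#' @param cds_start 0-based index of the first nucleotide of the start codon.
#' @param cds_end 0-based exclusive index one past the canonical stop codon.
#' @return An object of class `transcript_model`.
#' @export
#' @examples
#' t <- transcript_model("tx1", paste0("AAAAAA", "ATGGCTGCTGCTGCTGCTTGA", "AAA"),
#'                       cds_start = 6, cds_end = 27)
transcript_model <- function(id, seq, cds_start, cds_end) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- normalize_nt(seq)
  if (grepl("[^ACGT]", seq))
    stop("transcript '", id, "': sequence contains characters outside {A,C,G,T,U}")
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  n <- nchar(seq)
  if (is.na(cds_start) || is.na(cds_end) || cds_start < 0L ||
      cds_start >= cds_end || cds_end > n)
    stop("transcript '", id, "': CDS [", cds_start, ",", cds_end,
         ") is not a valid interval within [0,", n, ")")
  if ((cds_end - cds_start) %% 3L != 0L)
    stop("transcript '", id, "': CDS length ", cds_end - cds_start,
         " is not divisible by 3")
  stop1 <- substr(seq, cds_end - 2L, cds_end)
  if (!stop1 %in% STOP_CODONS)
    stop("transcript '", id, "': no canonical stop; CDS ends in '", stop1,
         "', expected one of ", paste(STOP_CODONS, collapse = "/"))
  structure(
    list(id = id, seq = seq, cds_start = cds_start, cds_end = cds_end),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$id, "\n", sep = "")
  cat("  length:   ", nchar(x$seq), " nt\n", sep = "")
  # report in 1-based closed coordinates for human readers
  cat("  CDS:      ", x$cds_start + 1L, "-", x$cds_end, " (1-based), ",
      (x$cds_end - x$cds_start) / 3L - 1L, " aa + stop\n", sep = "")
  cat("  stop 1:   ", substr(x$seq, x$cds_end - 2L, x$cds_end), "\n", sep = "")
  invisible(x)
}

#' Read a CDS annotation table
#'
#' Expects a tab-separated file with columns `transcript_id`, `cds_start`,
#' `cds_end` in 0-based half-open transcript coordinates (lines starting
#' with `#` are treated as comments).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with one row per transcript.
#' @export
read_cds_table <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("transcript_id", "cds_start", "cds_end")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("CDS table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Load transcripts from FASTA plus a CDS annotation table
#'
#' Reads transcript sequences and their CDS coordinates, validates every
#' record (coordinates in bounds, CDS length divisible by 3, CDS ending in
#' a canonical stop codon), and returns validated [transcript_model]
#' objects. `U` is normalised to `T` so RNA-alphabet FASTA is accepted.
#'
#' @param fasta_path Path to a (optionally gzipped) FASTA file.
#' @param cds_table_path Path to the CDS TSV (see [read_cds_table()]).
#' @return A named list of `transcript_model` objects, one per annotation row.
#' @export
load_transcripts <- function(fasta_path, cds_table_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  # keep only the first whitespace-delimited token of each FASTA header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- read_cds_table(cds_table_path)
  missing_seq <- setdiff(ann$transcript_id, names(seqs))
  if (length(missing_seq))
    stop("annotated transcript(s) absent from FASTA: ",
         paste(missing_seq, collapse = ", "))
  missing_ann <- setdiff(names(seqs), ann$transcript_id)
  if (length(missing_ann))
    stop("FASTA record(s) absent from CDS table: ",
         paste(missing_ann, collapse = ", "))
  out <- lapply(seq_len(nrow(ann)), function(i) {
    transcript_model(ann$transcript_id[i],
                     as.character(seqs[[ann$transcript_id[i]]]),
                     ann$cds_start[i], ann$cds_end[i])
  })
  names(out) <- ann$transcript_id
  out
}
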