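#' Locate the first downstream in-frame stop codon
#'
#' Scans codon triplets starting immediately after the canonical stop
#' codon, in the CDS reading frame only, towards the 3' end of the
#' transcript. The first triplet in `{TAA, TAG, TGA}` is "stop 2"; the
#' inter-stop-codon region (ISR) is the interval between the two stops and
#' encodes the C-terminal extension peptide appended upon readthrough.
#'
#' Only the CDS frame is scanned: out-of-frame readthrough reporters show
#' background signal only, so only in-frame extension is modelled.
#'
#' @param t A [transcript_model].
#' @return An object of class `isr_annotation` with fields
#'   `transcript_id`, `stop1_start`, `stop2_start`, `isr_start`, `isr_end`,
#'   `isr_len_nt`, `extension_len_aa`, `extension_peptide`, and the logical
#'   flag `no_downstream_stop`. When no in-frame stop exists before the
#'   transcript end the flag is `TRUE` and the ISR fields are `NA`.
#' @export
find_downstream_inframe_stop <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  n <- nchar(t$seq)
  stop1_start <- t$cds_end - 3L
  starts <- seq.int(t$cds_end, by = 3L, length.out = max(0L, (n - t$cds_end) %/% 3L))
  ann <- list(
    transcript_id = t$id,
    stop1_start = stop1_start,
    stop1_codon = substr(t$seq, stop1_start + 1L, stop1_start + 3L),
    stop2_start = NA_integer_,
    isr_start = NA_integer_,
    isr_end = NA_integer_,
    isr_len_nt = NA_integer_,
    extension_len_aa = NA_integer_,
    extension_peptide = NA_character_,
    no_downstream_stop = TRUE
  )
  if (length(starts)) {
    codons <- substring(t$seq, starts + 1L, starts + 3L)
    hit <- which(codons %in% STOP_CODONS)
    if (length(hit)) {
      s2 <- starts[hit[1L]]
      ann$stop2_start <- s2
      ann$isr_start <- t$cds_end
      ann$isr_end <- s2
      ann$isr_len_nt <- s2 - t$cds_end
      ann$extension_len_aa <- ann$isr_len_nt %/% 3L
      ann$no_downstream_stop <- FALSE
      class(ann) <- "isr_annotation"
      ann$extension_peptide <- translate_isr(t, ann)
      return(ann)
    }
  }
  structure(ann, class = "isr_annotation")
}

#' @export
print.isr_annotation <- function(x, ...) {
  cat("<isr_annotation> ", x$transcript_id, "\n", sep = "")
  if (isTRUE(x$no_downstream_stop)) {
    cat("  no in-frame stop codon downstream of the canonical stop\n")
  } else {
    # 1-based closed coordinates in the printed report
    cat("  stop 1 (", x$stop1_codon, "): ", x$stop1_start + 1L, "-",
        x$stop1_start + 3L, "\n", sep = "")
    cat("  stop 2: ", x$stop2_start + 1L, "-", x$stop2_start + 3L, "\n", sep = "")
    cat("  ISR:    ", x$isr_start + 1L, "-", x$isr_end, " (", x$isr_len_nt,
        " nt, ", x$extension_len_aa, " aa extension)\n", sep = "")
  }
  invisible(x)
}

#' Translate the inter-stop-codon region
#'
#' Standard genetic-code translation of the ISR. An annotation produced by
#' [find_downstream_inframe_stop()] cannot contain an internal stop (the
#' scan takes the first in-frame stop as the ISR boundary); encountering
#' one signals inconsistent, e.g. hand-edited, coordinates and is a hard
#' error.
#'
#' @param t A [transcript_model].
#' @param a An `isr_annotation` for `t` with an ISR present.
#' @return The extension peptide as an amino-acid string (may be `""` for
#'   adjacent stop codons).
#' @export
translate_isr <- function(t, a) {
  stopifnot(inherits(t, "transcript_model"), inherits(a, "isr_annotation"))
  if (isTRUE(a$no_downstream_stop))
    stop("transcript '", t$id, "': annotation has no ISR to translate")
  if (a$isr_len_nt == 0L) return("")
  nt <- substr(t$seq, a$isr_start + 1L, a$isr_end)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  if (grepl("*", aa, fixed = TRUE))
    stop("transcript '", t$id, "': internal stop codon inside the ISR; ",
         "annotation is inconsistent with the sequence")
  aa
}

#' Length of the C-terminally extended readthrough isoform
#'
#' @param canonical_aa Length of the canonical protein in amino acids.
#' @param extension_aa Length of the ISR-encoded extension in amino acids.
#' @return `canonical_aa + extension_aa`, the readthrough product length.
#' @export
#' @examples
#' extended_isoform_length(81, 89)  # 170
#' extended_isoform_length(54, 89)  # 143
extended_isoform_length <- function(canonical_aa, extension_aa) {
  canonical_aa <- as.integer(canonical_aa)
  extension_aa <- as.integer(extension_aa)
  if (anyNA(canonical_aa) || anyNA(extension_aa) ||
      any(canonical_aa < 0L) || any(extension_aa < 0L))
    stop("isoform lengths must be non-negative integers")
  canonical_aa + extension_aa
}

#' Write ISR annotations to a TSV report
#'
#' Coordinates in the file are 0-based half-open (stated in the header
#' comment); the print methods use 1-based closed coordinates instead.
#'
#' @param annotations List of `isr_annotation` objects.
#' @param path Output file path.
#' @return The data.frame that was written, invisibly.
#' @export
write_isr_table <- function(annotations, path) {
  df <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(transcript_id = a$transcript_id,
               stop1_start = a$stop1_start,
               stop1_codon = a$stop1_codon,
               stop2_start = a$stop2_start,
               isr_start = a$isr_start, isr_end = a$isr_end,
               isr_len_nt = a$isr_len_nt,
               extension_len_aa = a$extension_len_aa,
               extension_peptide = a$extension_peptide,
               no_downstream_stop = a$no_downstream_stop,
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 0-based, half-open", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
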