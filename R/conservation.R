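# Conservation scoring of the predicted extension peptide across species.
#
# Unaligned inputs are stacked into a pseudo-MSA by global pairwise
# alignment of every sequence against the first (reference) sequence with
# identity scoring: match +1, mismatch 0, gap -1. Insertions relative to
# the reference are dropped so every row has the reference length.

aa_identity_matrix <- function() {
  letters <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
               "P","S","T","W","Y","V","B","Z","X","*")
  m <- diag(1, length(letters))
  dimnames(m) <- list(letters, letters)
  m
}

#' Stack peptides into a reference-anchored pseudo-alignment
#'
#' Globally aligns each peptide to the first one (match +1, mismatch 0,
#' gap -1), keeps only columns present in the reference, and pads
#' deletions with `-`. Pre-aligned input can bypass this via
#' `prealigned = TRUE` in [score_conservation()].
#'
#' @param peptides Character vector of >= 2 amino-acid strings (gap-free).
#' @return Character vector of equal-length gapped strings, same names.
#' @export
align_to_reference <- function(peptides) {
  stopifnot(length(peptides) >= 2L)
  ref <- peptides[[1L]]
  sm <- aa_identity_matrix()
  out <- vapply(peptides, function(p) {
    if (identical(p, ref)) return(ref)
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(p),
      subject = Biostrings::AAString(ref),
      type = "global", substitutionMatrix = sm,
      gapOpening = 0, gapExtension = 1)
    pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
    sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
    paste(pat[sub != "-"], collapse = "")
  }, character(1))
  names(out) <- names(peptides)
  out
}

#' Score per-column conservation of extension peptides
#'
#' Computes, for every alignment column, the fraction of non-gap residues
#' matching the column's majority residue (ties broken alphabetically),
#' and flags columns at or above the conservation threshold `tau`.
#'
#' @param peptides Character vector of >= 2 amino-acid strings. If
#'   `prealigned = FALSE` (default) they are first stacked with
#'   [align_to_reference()]; otherwise they must already have equal length.
#' @param tau Conservation threshold in `[0, 1]`; default `0.8`.
#' @param prealigned Set `TRUE` when `peptides` are already aligned
#'   (gapped, equal length).
#' @return An object of class `conservation_profile` with fields
#'   `species_ids`, `aligned_peptides`, `majority_residue`,
#'   `column_identity`, `conserved_mask`, `tau`.
#' @export
score_conservation <- function(peptides, tau = 0.8, prealigned = FALSE) {
  if (length(peptides) < 2L)
    stop("conservation undefined for a single sequence")
  stopifnot(is.numeric(tau), tau >= 0, tau <= 1)
  if (is.null(names(peptides)) || any(!nzchar(names(peptides))))
    names(peptides) <- paste0("seq", seq_along(peptides))
  peptides <- toupper(peptides)
  if (prealigned) {
    if (length(unique(nchar(peptides))) != 1L)
      stop("prealigned peptides must all have the same length")
    aligned <- peptides
  } else {
    aligned <- align_to_reference(peptides)
  }
  mat <- do.call(rbind, strsplit(aligned, ""))
  ncol_aln <- ncol(mat)
  majority <- character(ncol_aln)
  identity <- numeric(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    res <- mat[, j]
    res <- res[res != "-"]
    if (!length(res)) {
      majority[j] <- "-"
      identity[j] <- NA_real_
      next
    }
    tab <- table(res)
    # which.max on a table breaks ties by order of the (sorted) names,
    # i.e. alphabetically
    majority[j] <- names(tab)[which.max(tab)]
    identity[j] <- max(tab) / length(res)
  }
  structure(
    list(species_ids = names(peptides),
         aligned_peptides = aligned,
         majority_residue = majority,
         column_identity = identity,
         conserved_mask = !is.na(identity) & identity >= tau,
         tau = tau),
    class = "conservation_profile"
  )
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("<conservation_profile> ", length(x$species_ids), " species, ",
      length(x$column_identity), " columns, tau = ", x$tau, "\n", sep = "")
  cat(sprintf("  mean column identity: %.3f; %d/%d columns conserved\n",
              mean(x$column_identity, na.rm = TRUE),
              sum(x$conserved_mask), length(x$conserved_mask)))
  invisible(x)
}

#' @export
as.data.frame.conservation_profile <- function(x, ...) {
  data.frame(column = seq_along(x$column_identity),
             majority_residue = x$majority_residue,
             identity = x$column_identity,
             conserved = x$conserved_mask,
             stringsAsFactors = FALSE)
}

#' Write a conservation profile to TSV
#' @param profile A `conservation_profile`.
#' @param path Output file path.
#' @return The written data.frame, invisibly.
#' @export
write_conservation_table <- function(profile, path) {
  df <- as.data.frame(profile)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
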