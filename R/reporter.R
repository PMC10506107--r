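# Dual-luciferase readthrough quantification and the small normalisation
# and statistics helpers used alongside it (delta-delta-Ct fold changes,
# densitometry normalisation, t-tests with Welch's correction).

#' Validate a dual-luciferase table
#'
#' @param df Data.frame with columns `construct`, `replicate`, `fluc`,
#'   `rluc` (luminescence units; `fluc >= 0`, `rluc > 0`).
#' @return The table with a derived `ratio = fluc / rluc` column, class
#'   `luciferase_table`.
#' @export
luciferase_table <- function(df) {
  need <- c("construct", "replicate", "fluc", "rluc")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("luciferase table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$fluc)) || any(df$fluc < 0))
    stop("fluc readings must be finite and >= 0")
  if (any(!is.finite(df$rluc)) || any(df$rluc <= 0))
    stop("rluc readings must be finite and > 0 (replicate(s): ",
         paste(head(df$replicate[!is.finite(df$rluc) | df$rluc <= 0], 3L),
               collapse = ", "), ")")
  df$ratio <- df$fluc / df$rluc
  structure(df, class = c("luciferase_table", "data.frame"))
}

#' Read a dual-luciferase TSV
#' @param path TSV with columns `construct`, `replicate`, `fluc`, `rluc`.
#' @return A `luciferase_table`.
#' @export
read_luciferase_table <- function(path) {
  luciferase_table(read.delim(path, comment.char = "#",
                              stringsAsFactors = FALSE))
}

#' Per-replicate FLuc/RLuc ratios for one construct
#'
#' @param table A `luciferase_table`.
#' @param construct Construct label.
#' @return Numeric vector of per-replicate `fluc/rluc` ratios, in row order.
#' @export
fluc_rluc_ratios <- function(table, construct) {
  stopifnot(inherits(table, "luciferase_table"))
  rows <- table$construct == construct
  if (!any(rows))
    stop("construct '", construct, "' not present in the table")
  table$ratio[rows]
}

#' Percent readthrough from reporter ratios
#'
#' The readthrough efficiency is the mean FLuc/RLuc ratio of the
#' "with-stop" construct expressed as a percentage of the mean FLuc/RLuc
#' ratio of the "no-stop" construct (which reads through constitutively):
#' `100 * mean(with_stop) / mean(no_stop)`. Means are arithmetic over
#' replicates; rounding to one decimal happens only at display.
#'
#' @param with_stop Numeric vector of per-replicate ratios for the
#'   stop-containing construct.
#' @param no_stop Numeric vector of per-replicate ratios for the no-stop
#'   normaliser construct.
#' @return An object of class `readthrough_estimate` with fields
#'   `percent_tcr`, `with_stop_mean`, `no_stop_mean`, `n_with`, `n_no`.
#' @export
#' @examples
#' percent_tcr(0.0705, 0.6347)  # 11.1 percent
percent_tcr <- function(with_stop, no_stop) {
  if (!length(with_stop) || !length(no_stop))
    stop("both constructs need at least one replicate ratio")
  stopifnot(is.numeric(with_stop), is.numeric(no_stop))
  m_with <- mean(with_stop)
  m_no <- mean(no_stop)
  if (!is.finite(m_no) || m_no <= 0)
    stop("mean no-stop ratio must be positive")
  structure(
    list(percent_tcr = 100 * m_with / m_no,
         with_stop_mean = m_with, no_stop_mean = m_no,
         n_with = length(with_stop), n_no = length(no_stop)),
    class = "readthrough_estimate"
  )
}

#' @export
print.readthrough_estimate <- function(x, ...) {
  cat(sprintf("%% readthrough: %s%%  (with-stop mean %.4f / no-stop mean %.4f; n = %d, %d)\n",
              format_percent_tcr(x$percent_tcr), x$with_stop_mean,
              x$no_stop_mean, x$n_with, x$n_no))
  invisible(x)
}

#' Display a percent-readthrough value at one decimal
#'
#' Percent values are reported truncated (not rounded) at the last
#' decimal: the published per-cell-line efficiencies are reproduced from
#' their construct means only under truncation (0.0273/0.3748 gives
#' 7.28%, reported as 7.2%), and truncation is consistent with all of
#' them.
#'
#' @param x Percent value(s).
#' @param digits Decimals to keep (default 1).
#' @return Character vector of formatted percentages.
#' @export
format_percent_tcr <- function(x, digits = 1L) {
  sprintf(paste0("%.", digits, "f"), trunc(x * 10^digits) / 10^digits)
}

#' Percent readthrough from a luciferase table
#'
#' Convenience wrapper around [percent_tcr()] that pulls per-replicate
#' ratios by construct label. When a background (e.g. vector-only)
#' construct label is supplied, its mean ratio is subtracted from every
#' replicate ratio of both constructs first; no background subtraction is
#' applied by default.
#'
#' @param table A `luciferase_table`.
#' @param with_stop,no_stop Construct labels.
#' @param background Optional background construct label.
#' @return A `readthrough_estimate`.
#' @export
percent_tcr_from_table <- function(table, with_stop, no_stop,
                                   background = NULL) {
  w <- fluc_rluc_ratios(table, with_stop)
  n <- fluc_rluc_ratios(table, no_stop)
  if (!is.null(background)) {
    bg <- mean(fluc_rluc_ratios(table, background))
    w <- w - bg
    n <- n - bg
  }
  percent_tcr(w, n)
}

#' Two-sample t-test with Welch's correction
#'
#' Two-sided t-test: unpaired with the Welch-Satterthwaite degrees of
#' freedom by default, the pooled-variance Student variant via
#' `var_equal = TRUE`, or a paired test (one-sample t on the differences)
#' via `paired = TRUE`. Degenerate zero-variance input is handled
#' explicitly: identical groups give `t = 0`, `p = 1`.
#'
#' @param a,b Numeric vectors (each of length >= 2; equal lengths when
#'   paired).
#' @param paired Paired test (default `FALSE`).
#' @param var_equal Pooled-variance Student test (default `FALSE`, i.e.
#'   Welch); ignored when `paired = TRUE`.
#' @return A list with `t`, `df`, `p`, and `method`.
#' @export
welch_ttest <- function(a, b, paired = FALSE, var_equal = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (paired && length(a) != length(b))
    stop("paired test requires equal group lengths")
  method <- if (paired) "paired t-test"
            else if (var_equal) "pooled-variance t-test"
            else "Welch two-sample t-test"
  degenerate <- if (paired) stats::var(a - b) == 0
                else stats::var(a) == 0 && stats::var(b) == 0
  if (degenerate) {
    d <- mean(a) - mean(b)
    n_df <- if (paired) length(a) - 1 else length(a) + length(b) - 2
    if (d == 0)
      return(list(t = 0, df = n_df, p = 1, method = method))
    return(list(t = sign(d) * Inf, df = n_df, p = 0, method = method))
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = var_equal,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, method = method)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Fold change of a target gene relative to a reference gene between a
#' treated and a control condition:
#' `ddct = (Ct_target - Ct_ref)_treated - (Ct_target - Ct_ref)_control`
#' and fold change `2^(-ddct)`. Vectorised over records.
#'
#' @param ct_target_treated,ct_ref_treated Ct values in the treated
#'   condition.
#' @param ct_target_control,ct_ref_control Ct values in the control
#'   condition.
#' @return Fold change(s), `2^(-ddct)`.
#' @export
#' @examples
#' ddct_fold_change(24, 18, 25, 18)  # one cycle later than control: 2
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  cts <- cbind(ct_target_treated, ct_ref_treated,
               ct_target_control, ct_ref_control)
  if (any(!is.finite(cts)))
    stop("all four Ct values must be present and finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Normalise a band density to its loading control
#'
#' @param band Band density (arbitrary units).
#' @param loading Loading-control (e.g. actin) density; must be > 0.
#' @return Relative density `band / loading`. Vectorised.
#' @export
densitometry_normalize <- function(band, loading) {
  if (any(!is.finite(loading)) || any(loading <= 0))
    stop("loading-control density must be > 0")
  band / loading
}
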