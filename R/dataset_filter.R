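#' Count zero trinucleotide OE ratios per 5'UTR
#'
#' A zero OE ratio of a start/stop trinucleotide is uninformative: it is not
#' possible to tell whether the motif is absent because of selection or
#' simply because the sequence is short. This counts, per row, how many of
#' the four trinucleotide OE ratios (AUG, UGA, UAA, UAG) are zero.
#' Dinucleotide OE ratios are never counted.
#'
#' @param ft A `feature_table` (or any data frame with the four `oe_*`
#'   trinucleotide columns).
#' @return Integer vector in `[0, 4]`, one entry per row.
#' @export
count_zero_trinucleotide_oe <- function(ft) {
  stopifnot(is.data.frame(ft), all(.OE_TRI_COLS %in% names(ft)))
  as.integer(rowSums(as.matrix(ft[, .OE_TRI_COLS, drop = FALSE]) == 0))
}

.set_filter_provenance <- function(out, ft, rule, keep) {
  prov <- attr(ft, "provenance")
  if (is.null(prov)) prov <- list()
  prov$filter <- list(rule = rule,
                      total = nrow(ft),
                      retained = sum(keep),
                      removed = sum(!keep))
  attributes(out)$provenance <- prov
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Remove 5'UTRs with more than one zero trinucleotide OE ratio
#'
#' The cleaning rule for 5'UTR feature tables: rows with more than
#' `max_zeros` zero OE ratios among the four trinucleotides are excluded
#' before regression, because such rows are dominated by short sequences
#' whose motif content is uninformative about selection. At most one zero is
#' tolerated by default.
#'
#' @param ft A `feature_table`.
#' @param max_zeros Maximum tolerated number of zero trinucleotide OE ratios
#'   (default 1).
#' @return The filtered `feature_table`; retained/removed counts are recorded
#'   in the provenance attribute (see [filter_report()]).
#' @export
apply_zero_oe_filter <- function(ft, max_zeros = 1L) {
  stopifnot(is.data.frame(ft), nrow(ft) > 0L)
  keep <- count_zero_trinucleotide_oe(ft) <= max_zeros
  if (!any(keep)) {
    stop("empty dataset after filtering: every row has more than ",
         max_zeros, " zero trinucleotide OE ratio(s)", call. = FALSE)
  }
  out <- as.data.frame(ft)[keep, , drop = FALSE]
  rownames(out) <- NULL
  .set_filter_provenance(out, ft, "zero_oe", keep)
}

#' Remove 5'UTRs shorter than a length threshold
#'
#' Alternative cleaning rule that excludes sequences below a fixed length.
#' Compared with [apply_zero_oe_filter()], hard length thresholds skew the
#' log-length distribution away from normality (visible through
#' [length_distribution_report()]), so the zero-OE rule is the default in
#' [run_pipeline()]; this filter exists to reproduce that comparison.
#'
#' @param ft A `feature_table`.
#' @param min_length Minimum retained length in nucleotides (default 30).
#' @return The filtered `feature_table` with provenance updated.
#' @export
apply_length_filter <- function(ft, min_length = 30L) {
  stopifnot(is.data.frame(ft), nrow(ft) > 0L, "length" %in% names(ft))
  keep <- ft$length >= min_length
  if (!any(keep)) {
    stop("empty dataset after filtering: every row is shorter than ",
         min_length, " nt", call. = FALSE)
  }
  out <- as.data.frame(ft)[keep, , drop = FALSE]
  rownames(out) <- NULL
  .set_filter_provenance(out, ft, "length", keep)
}

#' Filtering outcome of a feature table
#'
#' @param ft A filtered `feature_table`.
#' @return One-row data frame with rule, total, retained and removed counts,
#'   or `NULL` if the table has not been filtered.
#' @export
filter_report <- function(ft) {
  filt <- attr(ft, "provenance")$filter
  if (is.null(filt)) return(NULL)
  data.frame(rule = filt$rule, total = filt$total,
             retained = filt$retained, removed = filt$removed,
             stringsAsFactors = FALSE)
}

#' Length distribution and log-normality diagnostics
#'
#' Empirical quantiles of raw and log10 lengths, plus a Shapiro-Francia-type
#' normality statistic for the log10 lengths: the correlation between the
#' sorted values and the corresponding standard normal quantiles
#' (`qnorm(ppoints(n, a = 3/8))`). Values near 1 indicate that log10 length
#' is close to normal — the working assumption of the linear regression —
#' and the statistic makes filtering strategies comparable (a hard length
#' cutoff visibly depresses it relative to the zero-OE rule).
#'
#' @param ft A `feature_table`.
#' @param quantiles Fractions at which to evaluate the empirical quantiles.
#' @return A `length_report` list with elements `quantiles` (data frame with
#'   columns `quantile`, `length`, `log10_length`), `normality_r` and `n`.
#' @export
length_distribution_report <- function(ft,
                                       quantiles = c(0.05, 0.25, 0.5,
                                                     0.75, 0.95)) {
  stopifnot(is.data.frame(ft), nrow(ft) > 0L,
            all(c("length", "log10_length") %in% names(ft)),
            all(quantiles >= 0 & quantiles <= 1))
  qdf <- data.frame(quantile = quantiles,
                    length = unname(quantile(ft$length, quantiles)),
                    log10_length = unname(quantile(ft$log10_length,
                                                   quantiles)))
  x <- sort(ft$log10_length)
  n <- length(x)
  r <- if (n >= 3L && sd(x) > 0) {
    cor(x, qnorm(stats::ppoints(n, a = 3 / 8)))
  } else {
    NA_real_
  }
  structure(list(quantiles = qdf, normality_r = r, n = n),
            class = "length_report")
}

#' @export
print.length_report <- function(x, ...) {
  cat(sprintf("Length distribution over %d 5'UTR(s)\n", x$n))
  print(x$quantiles, row.names = FALSE, ...)
  cat(sprintf("log10-length normality correlation: %.4f\n", x$normality_r))
  invisible(x)
}
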