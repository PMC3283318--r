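#' Per-sequence nucleotide frequencies
#'
#' Exact base counts divided by sequence length. These frequencies are the
#' `f_i` entering the expected motif counts and the minimal-length statistic.
#'
#' @param sequence A single RNA string over `A/C/G/U`.
#' @return Named numeric vector of fractions for `A`, `C`, `G`, `U`,
#'   summing to 1.
#' @export
#' @examples
#' nucleotide_frequencies("AUGAUG")
nucleotide_frequencies <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("degenerate sequence: length 0", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  counts <- tabulate(match(chars, .RNA_BASES), nbins = 4L)
  if (sum(counts) != length(chars)) {
    stop("sequence contains characters outside A/C/G/U", call. = FALSE)
  }
  setNames(counts / length(chars), .RNA_BASES)
}

#' Observed count of a motif (overlapping occurrences)
#'
#' Counts every start position at which the motif occurs, so overlapping
#' occurrences all count — the usual convention for CpG-style
#' observed/expected statistics.
#'
#' @param sequence A single RNA string.
#' @param motif RNA motif of length `k` (di- or trinucleotide in practice,
#'   any `k >= 1` accepted).
#' @return Integer count; 0 when the motif is longer than the sequence.
#' @export
#' @examples
#' observed_count("AUGAUG", "AUG")  # 2
#' observed_count("UUUU", "UU")     # 3 (overlaps counted)
observed_count <- function(sequence, motif) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  .motif_bases(motif)
  if (nchar(motif) > nchar(sequence)) return(0L)
  as.integer(Biostrings::countPattern(motif, Biostrings::RNAString(sequence)))
}

#' Expected count of a motif under per-sequence base frequencies
#'
#' The expected number of occurrences of a k-mer in a sequence of length `L`
#' with base frequencies `f` is `L * prod(f[bases of motif])` — e.g. for AUG,
#' `L * f_A * f_U * f_G`. An alternative convention using the number of
#' sliding windows (`L - k + 1`) instead of `L` is available; the two differ
#' negligibly for realistic 5'UTR lengths.
#'
#' @param freqs Named base frequencies as returned by
#'   [nucleotide_frequencies()].
#' @param L Sequence length (>= 1).
#' @param motif RNA motif.
#' @param convention `"length"` (default, `L` windows) or `"windows"`
#'   (`L - k + 1` windows).
#' @return Nonnegative real expected count.
#' @export
#' @examples
#' f <- nucleotide_frequencies("AUGAUG")
#' expected_count(f, 6, "AUG")  # 6 * (1/3)^3 = 2/9
expected_count <- function(freqs, L, motif,
                           convention = c("length", "windows")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(freqs), all(.RNA_BASES %in% names(freqs)), L >= 1)
  bases <- .motif_bases(motif)
  wins <- if (convention == "length") L else max(L - length(bases) + 1, 0)
  wins * prod(freqs[bases])
}

#' Observed-to-expected ratio of a motif
#'
#' Observed overlapping occurrence count divided by the expected count under
#' the sequence's own base frequencies. When the expected count is 0 (a base
#' required by the motif is absent, so the observed count is necessarily 0
#' too) the ratio is defined as 0. A sequence shorter than the motif yields 0
#' with a `degenerate` attribute.
#'
#' @inheritParams observed_count
#' @inheritParams expected_count
#' @return Nonnegative real; near 1 for motifs occurring at chance rates.
#' @export
#' @examples
#' oe_ratio("AUGAUG", "AUG")  # 2 / (2/9) = 9
oe_ratio <- function(sequence, motif, convention = c("length", "windows")) {
  convention <- match.arg(convention)
  L <- nchar(sequence)
  if (L < nchar(motif)) {
    return(structure(0, degenerate = TRUE))
  }
  freqs <- nucleotide_frequencies(sequence)
  e <- expected_count(freqs, L, motif, convention)
  if (e == 0) 0 else observed_count(sequence, motif) / e
}

#' G+C content from base frequencies
#'
#' @inheritParams expected_count
#' @return Fraction of G plus C in `[0, 1]`.
#' @export
gc_content <- function(freqs) {
  stopifnot(is.numeric(freqs), all(c("G", "C") %in% names(freqs)))
  unname(freqs[["G"]] + freqs[["C"]])
}

#' Minimal sequence length for a motif to occur once by chance
#'
#' Setting the expected count `L * prod(f[bases])` to one and solving for `L`
#' gives the shortest sequence in which the motif is expected to occur by
#' chance: the reciprocal of the product of the base frequencies. Below this
#' length, selection on the motif is unlikely to be visible because the motif
#' rarely arises at all.
#'
#' @inheritParams expected_count
#' @return Positive real, or `Inf` when a required base has frequency 0.
#' @export
#' @examples
#' minimal_length(c(A = .25, C = .25, G = .25, U = .25), "AUG")  # 64
minimal_length <- function(freqs, motif) {
  stopifnot(is.numeric(freqs), all(.RNA_BASES %in% names(freqs)))
  p <- prod(freqs[.motif_bases(motif)])
  if (p == 0) Inf else 1 / p
}

# 1-based start positions of fixed motif matches (motifs used here cannot
# self-overlap, so non-overlapping gregexpr matching is exhaustive)
.match_starts <- function(sequence, motif) {
  m <- gregexpr(motif, sequence, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Find upstream open reading frames in a 5'UTR
#'
#' A uORF is an AUG followed by an in-frame stop codon (UAA, UAG or UGA)
#' within the 5'UTR, with at least one non-stop codon in between. For every
#' AUG the scan takes the first in-frame stop downstream (ribosome
#' termination semantics); AUGs whose first in-frame stop is immediate (no
#' intervening codon) or that lack an in-frame stop inside the sequence yield
#' no interval. uORFs whose stop codon would lie in the downstream coding
#' sequence cannot be seen from 5'UTR sequence alone and are not reported.
#'
#' @param sequence A single RNA string.
#' @return Data frame with 0-based columns `start` (offset of the A of the
#'   AUG) and `stop_start` (offset of the first base of the in-frame stop);
#'   zero rows when no uORF exists.
#' @export
#' @examples
#' find_uorfs("AUGAAAUAA")  # one uORF: start 0, stop_start 6
#' find_uorfs("AUGUAA")     # none: no codon between start and stop
find_uorfs <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  empty <- data.frame(start = integer(0), stop_start = integer(0))
  L <- nchar(sequence)
  if (L < 9L) return(empty)
  augs <- .match_starts(sequence, "AUG")
  if (!length(augs)) return(empty)
  stops <- sort(unique(unlist(lapply(.STOP_CODONS, .match_starts,
                                     sequence = sequence))))
  if (!length(stops)) return(empty)
  out_start <- integer(0)
  out_stop <- integer(0)
  for (p in augs) {
    q <- stops[stops > p & (stops - p) %% 3L == 0L & stops + 2L <= L]
    if (length(q)) {
      q1 <- q[1L]
      if (q1 - p >= 6L) {
        out_start <- c(out_start, p - 1L)
        out_stop <- c(out_stop, q1 - 1L)
      }
    }
  }
  data.frame(start = out_start, stop_start = out_stop)
}

#' Export uORF intervals in BED format
#'
#' One BED line per uORF (0-based, half-open; the interval spans start codon
#' through stop codon inclusive). The chromosome column carries the
#' transcript identifier since coordinates are relative to the 5'UTR.
#'
#' @param records A `utr_records` data frame.
#' @param path Optional output path; when `NULL` the BED data frame is
#'   returned without writing.
#' @return Data frame of BED fields (invisibly when `path` is given).
#' @export
uorfs_to_bed <- function(records, path = NULL) {
  stopifnot(is.data.frame(records),
            all(c("transcript_id", "sequence") %in% names(records)))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    u <- find_uorfs(records$sequence[i])
    if (!nrow(u)) return(NULL)
    data.frame(chrom = records$transcript_id[i],
               chromStart = u$start,
               chromEnd = u$stop_start + 3L,
               name = sprintf("uORF_%s_%d", records$transcript_id[i],
                              seq_len(nrow(u))),
               score = 0L,
               strand = "+",
               stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(bed)) {
    bed <- data.frame(chrom = character(), chromStart = integer(),
                      chromEnd = integer(), name = character(),
                      score = integer(), strand = character())
  }
  if (!is.null(path)) {
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    return(invisible(bed))
  }
  bed
}

.feature_columns <- function() {
  c("gene_id", "transcript_id", "length", "log10_length", "gc_content",
    .OE_TRI_COLS, .OE_DI_COLS, "uorf_present", "n_zero_tri_oe")
}

#' Compute the full feature table for a set of 5'UTR records
#'
#' One row per record: log10 length (the regression response), G+C content,
#' observed-to-expected ratios of the four trinucleotides (AUG, UGA, UAA,
#' UAG) and four dinucleotides (CG, UG, UU, UA), the uORF presence indicator,
#' and the count of zero trinucleotide OE ratios used by the cleaning rule.
#' Records shorter than 3 nt cannot support a trinucleotide window and are
#' excluded with a warning.
#'
#' Counting is vectorized through Biostrings; overlapping motif occurrences
#' all count, and expected counts follow the `L * prod(f)` convention (see
#' [expected_count()]).
#'
#' @param records A `utr_records` data frame (or any data frame with
#'   `gene_id`, `transcript_id`, `sequence` columns).
#' @param convention Expected-count convention, see [expected_count()].
#' @param include_uorf Compute the uORF presence column (the per-record ORF
#'   scan is the most expensive feature; set `FALSE` to skip it when the
#'   indicator is not needed, leaving `NA`s).
#' @return A `feature_table` data frame; provenance (input counts, dropped
#'   short records, convention) is stored in the `provenance` attribute.
#' @export
feature_table <- function(records, convention = c("length", "windows"),
                          include_uorf = TRUE) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            all(c("gene_id", "transcript_id", "sequence") %in% names(records)))

  L_all <- nchar(records$sequence)
  short <- L_all < 3L
  if (all(short)) {
    stop("no record is long enough (>= 3 nt) for trinucleotide features",
         call. = FALSE)
  }
  if (any(short)) {
    warning(sprintf("excluded %d record(s) shorter than 3 nt", sum(short)),
            call. = FALSE)
  }
  rec <- as.data.frame(records)[!short, , drop = FALSE]
  L <- L_all[!short]

  x <- Biostrings::RNAStringSet(rec$sequence)
  counts <- Biostrings::letterFrequency(x, .RNA_BASES)
  f <- counts / L
  tri_obs <- Biostrings::oligonucleotideFrequency(x, 3L)[, .TRI_MOTIFS,
                                                         drop = FALSE]
  di_obs <- Biostrings::oligonucleotideFrequency(x, 2L)[, .DI_MOTIFS,
                                                        drop = FALSE]

  wins3 <- if (convention == "length") L else L - 2L
  wins2 <- if (convention == "length") L else L - 1L
  oe_block <- function(obs, motifs, wins) {
    out <- matrix(0, nrow(obs), length(motifs),
                  dimnames = list(NULL, paste0("oe_", tolower(motifs))))
    for (m in seq_along(motifs)) {
      bases <- strsplit(motifs[m], "", fixed = TRUE)[[1L]]
      e <- wins * apply(f[, bases, drop = FALSE], 1L, prod)
      out[, m] <- ifelse(e == 0, 0, obs[, m] / e)
    }
    out
  }
  tri_oe <- oe_block(tri_obs, .TRI_MOTIFS, wins3)
  di_oe <- oe_block(di_obs, .DI_MOTIFS, wins2)

  uorf <- if (include_uorf) {
    vapply(rec$sequence, function(s) as.integer(nrow(find_uorfs(s)) > 0L),
           integer(1L), USE.NAMES = FALSE)
  } else {
    rep(NA_integer_, nrow(rec))
  }

  ft <- data.frame(gene_id = rec$gene_id,
                   transcript_id = rec$transcript_id,
                   length = L,
                   log10_length = log10(L),
                   gc_content = unname(f[, "G"] + f[, "C"]),
                   stringsAsFactors = FALSE)
  ft <- cbind(ft, as.data.frame(tri_oe), as.data.frame(di_oe))
  ft$uorf_present <- uorf
  ft$n_zero_tri_oe <- as.integer(rowSums(tri_oe == 0))
  rownames(ft) <- NULL

  structure(ft,
            provenance = list(source = attr(records, "source"),
                              n_input = nrow(records),
                              n_short_dropped = sum(short),
                              convention = convention,
                              include_uorf = include_uorf,
                              filter = NULL),
            class = c("feature_table", "data.frame"))
}

#' Feature vector of a single 5'UTR record
#'
#' Convenience wrapper around [feature_table()] for one record.
#'
#' @param record One-row data frame, or a list/vector with `gene_id`,
#'   `transcript_id` and `sequence` entries.
#' @inheritParams feature_table
#' @return One-row `feature_table`.
#' @export
#' @examples
#' feature_vector(list(gene_id = "g1", transcript_id = "t1",
#'                     sequence = "AUGAUG"))
feature_vector <- function(record, convention = c("length", "windows")) {
  if (!is.data.frame(record)) {
    record <- data.frame(gene_id = record$gene_id,
                         transcript_id = record$transcript_id,
                         sequence = record$sequence,
                         stringsAsFactors = FALSE)
  }
  stopifnot(nrow(record) == 1L)
  if (nchar(record$sequence) < 3L) {
    stop("sequence too short for trinucleotide features (need >= 3 nt)",
         call. = FALSE)
  }
  feature_table(record, convention = match.arg(convention))
}

#' Write a feature table as TSV
#'
#' @param ft A `feature_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  out <- as.data.frame(ft)
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17L,
                                                  scientific = FALSE,
                                                  trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.feature_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("5'UTR feature table: %d row(s)\n", nrow(x)))
  if (!is.null(prov$filter)) {
    cat(sprintf("  filtered by %s rule: %d retained / %d removed\n",
                prov$filter$rule, prov$filter$retained, prov$filter$removed))
  }
  print(head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("  ... and %d more row(s)\n", nrow(x) - 6L))
  invisible(x)
}
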