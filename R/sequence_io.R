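#' Header parsing rule for 5'UTR FASTA files
#'
#' FASTA dialects differ in how gene and transcript identifiers are packed
#' into the record header. A header rule names the field delimiter and the
#' (1-based) positions of the gene and transcript fields within the first
#' whitespace-delimited token of the header. Headers with a single field use
#' that field as both identifiers.
#'
#' @param delim Field delimiter inside the header token (fixed string).
#' @param gene_field 1-based index of the gene identifier field.
#' @param transcript_field 1-based index of the transcript identifier field.
#' @return An object of class `utr_header_rule`.
#' @export
#' @examples
#' header_rule()                      # ">gene|transcript"
#' header_rule(delim = ":", gene_field = 2, transcript_field = 1)
header_rule <- function(delim = "|", gene_field = 1L, transcript_field = 2L) {
  stopifnot(is.character(delim), length(delim) == 1L, nzchar(delim),
            gene_field >= 1L, transcript_field >= 1L)
  structure(list(delim = delim,
                 gene_field = as.integer(gene_field),
                 transcript_field = as.integer(transcript_field)),
            class = "utr_header_rule")
}

.new_utr_records <- function(df, dropped = NULL, source = NA_character_) {
  rownames(df) <- NULL
  structure(df,
            dropped = dropped,
            source = source,
            class = c("utr_records", "data.frame"))
}

#' Read and validate a FASTA file of 5'UTR sequences
#'
#' Reads plain or gzipped FASTA, uppercases sequences and converts DNA `T` to
#' RNA `U` so that all downstream motifs are RNA-spelled. Records whose
#' sequence contains any character outside `A/C/G/T/U` after uppercasing
#' (ambiguity codes such as `N`, or gaps) are dropped with a warning, because
#' per-sequence base frequencies would be ill-defined; the dropped records
#' are tallied in the drop report (see [drop_report()]).
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @param rule A [header_rule()] describing how to recover gene and
#'   transcript identifiers from record headers.
#' @return A `utr_records` data frame with columns `gene_id`,
#'   `transcript_id`, `sequence` (RNA over A/C/G/U) and `length`, carrying a
#'   drop report and the source path as attributes.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1|t1", "acgt", ">g2|t1", "AUGGCC"), fa)
#' read_utr_fasta(fa)
read_utr_fasta <- function(path, rule = header_rule()) {
  stopifnot(inherits(rule, "utr_header_rule"))
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read FASTA file: ", path, call. = FALSE)
  }
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("failed to parse FASTA file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(raw) == 0L) {
    stop("no records in FASTA file: ", path, call. = FALSE)
  }

  seqs <- chartr("T", "U", toupper(as.character(raw)))
  headers <- names(raw)
  if (is.null(headers)) headers <- rep("", length(raw))
  token <- sub("\\s.*$", "", headers)

  parts <- strsplit(token, rule$delim, fixed = TRUE)
  pick <- function(p, i) {
    if (length(p) >= i && nzchar(p[i])) p[i] else NA_character_
  }
  gene_id <- vapply(parts, pick, "", i = rule$gene_field)
  transcript_id <- vapply(parts, pick, "", i = rule$transcript_field)
  # single-token headers (no delimiter): the token serves as both identifiers
  gene_id[is.na(gene_id)] <- token[is.na(gene_id)]
  transcript_id[is.na(transcript_id)] <- token[is.na(transcript_id)]

  ok_alpha <- grepl("^[ACGU]+$", seqs)
  ok_id <- nzchar(gene_id) & nzchar(transcript_id)
  keep <- ok_alpha & ok_id

  reason <- character(length(raw))
  reason[!ok_alpha] <- "empty sequence or characters outside A/C/G/T/U"
  reason[!ok_id] <- "unparseable header (empty gene or transcript id)"
  dropped <- data.frame(gene_id = gene_id[!keep],
                        transcript_id = transcript_id[!keep],
                        header = headers[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(dropped) > 0L) {
    warning(sprintf("dropped %d of %d FASTA record(s) during validation",
                    nrow(dropped), length(raw)), call. = FALSE)
  }
  if (!any(keep)) {
    stop("no valid records remain after validation: ", path, call. = FALSE)
  }

  df <- data.frame(gene_id = gene_id[keep],
                   transcript_id = transcript_id[keep],
                   sequence = unname(seqs[keep]),
                   length = nchar(seqs[keep]),
                   stringsAsFactors = FALSE)
  .new_utr_records(df, dropped = dropped, source = path)
}

#' Write 5'UTR records to FASTA
#'
#' Headers are reassembled as `gene<delim>transcript` using the supplied
#' header rule's delimiter.
#'
#' @param records A `utr_records` data frame.
#' @param path Output FASTA path.
#' @param rule A [header_rule()]; only its delimiter is used.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(records, path, rule = header_rule()) {
  stopifnot(is.data.frame(records),
            all(c("gene_id", "transcript_id", "sequence") %in% names(records)))
  x <- Biostrings::RNAStringSet(records$sequence)
  names(x) <- paste(records$gene_id, records$transcript_id, sep = rule$delim)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Drop report of a record set or feature table
#'
#' @param x A `utr_records` or `feature_table` object.
#' @return A data frame of dropped records and reasons (possibly empty).
#' @export
drop_report <- function(x) {
  d <- attr(x, "dropped")
  if (is.null(d)) {
    d <- data.frame(gene_id = character(), transcript_id = character(),
                    header = character(), reason = character(),
                    stringsAsFactors = FALSE)
  }
  d
}

#' Write the drop report as TSV
#'
#' @param x Object carrying a drop report.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_drop_report <- function(x, path) {
  write.table(drop_report(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Keep one transcript per gene
#'
#' Genes represented by several transcripts would be over-weighted in
#' downstream per-gene analyses, so one transcript is selected uniformly at
#' random per gene. The choice is driven by an explicit seed and the output
#' is sorted by gene identifier, so the same input and seed always give the
#' same result. The caller's random-number state is left untouched.
#'
#' @param records A `utr_records` data frame.
#' @param seed Integer seed for the transcript draw.
#' @return A `utr_records` data frame with exactly one row per distinct
#'   `gene_id`, sorted by `gene_id`. The number of discarded transcripts is
#'   recorded in the `n_transcripts_dropped` attribute.
#' @export
select_one_transcript_per_gene <- function(records, seed) {
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            all(c("gene_id", "transcript_id") %in% names(records)),
            all(nzchar(records$gene_id)))
  seed <- as.integer(seed)
  by_gene <- split(seq_len(nrow(records)), records$gene_id)
  idx <- withr::with_seed(seed, vapply(by_gene, function(i) {
    if (length(i) == 1L) i else i[sample.int(length(i), 1L)]
  }, integer(1L)))
  out <- as.data.frame(records)[idx, , drop = FALSE]
  out <- .new_utr_records(out,
                          dropped = attr(records, "dropped"),
                          source = attr(records, "source"))
  attr(out, "selection_seed") <- seed
  attr(out, "n_transcripts_dropped") <- nrow(records) - length(idx)
  out
}

#' @export
print.utr_records <- function(x, ...) {
  cat(sprintf("5'UTR records: %d sequence(s), %d gene(s)\n",
              nrow(x), length(unique(x$gene_id))))
  d <- drop_report(x)
  if (nrow(d)) cat(sprintf("  (%d record(s) dropped during import)\n", nrow(d)))
  print(head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("  ... and %d more row(s)\n", nrow(x) - 6L))
  invisible(x)
}
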