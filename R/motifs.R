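# Motif sets tracked throughout the package. The trinucleotides are the start
# codon and the three stop codons as they appear in mRNA space; the
# dinucleotides are the methylation-related CG/UG pair and the
# mRNA-destabilizing UU/UA pair.

.TRI_MOTIFS <- c("AUG", "UGA", "UAA", "UAG")
.DI_MOTIFS <- c("CG", "UG", "UU", "UA")
.ALL_MOTIFS <- c(.TRI_MOTIFS, .DI_MOTIFS)
.RNA_BASES <- c("A", "C", "G", "U")
.STOP_CODONS <- c("UAA", "UAG", "UGA")

# oe_* column names in a feature table, in candidate-predictor order
.OE_TRI_COLS <- paste0("oe_", tolower(.TRI_MOTIFS))
.OE_DI_COLS <- paste0("oe_", tolower(.DI_MOTIFS))

#' Motifs tracked by the 5'UTR feature computations
#'
#' @return A list with components `tri` (start/stop trinucleotides
#'   `AUG`, `UGA`, `UAA`, `UAG`) and `di` (dinucleotides `CG`, `UG`,
#'   `UU`, `UA`), spelled in RNA space.
#' @export
#' @examples
#' utr_motifs()
utr_motifs <- function() {
  list(tri = .TRI_MOTIFS, di = .DI_MOTIFS)
}

#' Default candidate predictors of log10 5'UTR length
#'
#' The nine composition features entered into the full regression model:
#' G+C content and the observed-to-expected ratios of the four
#' trinucleotides and four dinucleotides. Optionally appends the upstream-ORF
#' presence indicator.
#'
#' @param include_uorf Append `"uorf_present"` to the predictor set.
#' @return Character vector of feature-table column names.
#' @export
default_predictors <- function(include_uorf = FALSE) {
  preds <- c("gc_content", .OE_TRI_COLS, .OE_DI_COLS)
  if (include_uorf) preds <- c(preds, "uorf_present")
  preds
}

# split a motif string into single bases, validating the alphabet
.motif_bases <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif)) {
    stop("motif must be a single non-empty RNA string", call. = FALSE)
  }
  bases <- strsplit(motif, "", fixed = TRUE)[[1L]]
  bad <- setdiff(bases, .RNA_BASES)
  if (length(bad)) {
    stop("motif contains non-RNA characters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bases
}
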