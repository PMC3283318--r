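# Synthetic 5'UTR sets with known, planted statistical structure. The
# generative model mirrors the regression model exactly: per-gene covariates
# (G+C content, per-sequence motif suppression/enrichment factors) are drawn,
# log10 length is a planted linear combination of them plus Gaussian noise,
# and sequences of the resulting lengths are emitted with the requested
# composition. Features are then re-measured from the realized sequences, so
# recovery of the planted coefficients is attenuated by measurement noise —
# just as in real data, where features are measured, not known.

.covariate_names <- function() {
  c("(Intercept)", "gc", paste0("s_", tolower(.ALL_MOTIFS)))
}

#' Specification of a synthetic 5'UTR dataset
#'
#' Bundles the generative parameters: number of genes, a Beta model for
#' per-gene G+C content, per-motif suppression/enrichment factors, a planted
#' coefficient vector linking log10 length to the generative covariates, the
#' noise standard deviation, the transcripts-per-gene model and the seed.
#'
#' Lengths are log-normal by construction: with the default intercept
#' `log10(160)` and `noise_sd = 0.4` (log10 scale), half the generated 5'UTRs
#' are shorter than 160 nt and the raw length distribution is strongly
#' right-skewed, matching the shape of curated 5'UTR collections. G+C varies
#' across sequences as Beta(10, 10) (mean 0.5, sd ~0.11). All motif modifiers
#' default to 1, which reproduces the iid base model exactly.
#'
#' @param n_genes Number of genes.
#' @param gc_shape1,gc_shape2 Beta parameters for per-gene G+C content.
#' @param motif_modifiers Named list over motifs from [utr_motifs()]. Each
#'   entry is either a single factor `s >= 0` applied to every sequence
#'   (`s = 1` neutral, `s = 0` full suppression, `s > 1` enrichment), or a
#'   length-2 range from which a per-sequence factor is drawn uniformly
#'   (making the factor a gene-level covariate that can carry a planted
#'   coefficient).
#' @param planted_beta Named coefficient vector over `"(Intercept)"`, `"gc"`
#'   and `"s_<motif>"` names (e.g. `"s_aug"`); the generative truth for
#'   log10 length.
#' @param noise_sd Standard deviation of the Gaussian noise added to log10
#'   length.
#' @param transcripts_per_gene Either a single positive integer, or a named
#'   numeric vector of probabilities whose names are transcript counts
#'   (e.g. `c("1" = .8, "2" = .15, "3" = .05)`).
#' @param max_passes Cap on motif-modifier resampling passes per sequence
#'   set; realized motif counts are recorded, not assumed.
#' @param seed Integer seed; all randomness in [generate_dataset()] derives
#'   from it.
#' @return A `synthetic_spec` object.
#' @export
#' @examples
#' synthetic_spec(n_genes = 100, seed = 7,
#'                motif_modifiers = list(AUG = c(0.3, 1)),
#'                planted_beta = c("(Intercept)" = 2.5, gc = 1.5,
#'                                 s_aug = -1))
synthetic_spec <- function(n_genes = 2000L,
                           gc_shape1 = 10,
                           gc_shape2 = 10,
                           motif_modifiers = list(),
                           planted_beta = c("(Intercept)" = log10(160)),
                           noise_sd = 0.4,
                           transcripts_per_gene = 1L,
                           max_passes = 10L,
                           seed = 1L) {
  stopifnot(n_genes >= 1L, gc_shape1 > 0, gc_shape2 > 0, noise_sd >= 0,
            max_passes >= 1L)
  if (length(motif_modifiers)) {
    stopifnot(!is.null(names(motif_modifiers)),
              all(names(motif_modifiers) %in% .ALL_MOTIFS))
    for (v in motif_modifiers) {
      stopifnot(is.numeric(v), length(v) %in% 1:2, all(v >= 0))
    }
  }
  stopifnot(is.numeric(planted_beta), !is.null(names(planted_beta)),
            "(Intercept)" %in% names(planted_beta),
            all(names(planted_beta) %in% .covariate_names()))
  if (is.null(names(transcripts_per_gene))) {
    stopifnot(length(transcripts_per_gene) == 1L, transcripts_per_gene >= 1L)
    transcripts_per_gene <- as.integer(transcripts_per_gene)
  } else {
    stopifnot(all(transcripts_per_gene >= 0),
              sum(transcripts_per_gene) > 0,
              !anyNA(as.integer(names(transcripts_per_gene))))
  }
  structure(list(n_genes = as.integer(n_genes),
                 gc_shape1 = gc_shape1,
                 gc_shape2 = gc_shape2,
                 motif_modifiers = motif_modifiers,
                 planted_beta = planted_beta,
                 noise_sd = noise_sd,
                 transcripts_per_gene = transcripts_per_gene,
                 max_passes = as.integer(max_passes),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("Synthetic 5'UTR spec: %d gene(s), seed %d\n", x$n_genes,
              x$seed))
  cat(sprintf("  G+C ~ Beta(%g, %g); noise sd %g (log10 scale)\n",
              x$gc_shape1, x$gc_shape2, x$noise_sd))
  cat("  planted beta:",
      paste(sprintf("%s=%.4g", names(x$planted_beta), x$planted_beta),
            collapse = ", "), "\n")
  if (length(x$motif_modifiers)) {
    cat("  motif modifiers:",
        paste(sprintf("%s=[%s]", names(x$motif_modifiers),
                      vapply(x$motif_modifiers, paste, "", collapse = ",")),
              collapse = " "), "\n")
  }
  invisible(x)
}

# ---- vectorized sequence generation core ------------------------------------
# Bases are kept as integer codes 1..4 = A, C, G, U in one flat vector for all
# sequences; seqid maps every base to its sequence. Motif occurrences are
# located by vectorized code comparison; suppression is a thinning pass (each
# occurrence is tested once and kept with probability s, rejected windows are
# redrawn and only the perturbed neighbourhoods rescanned), enrichment plants
# extra occurrences at Poisson rates.

.motif_codes <- function(motif) match(.motif_bases(motif), .RNA_BASES)

# start positions of a coded motif in the flat base vector, restricted to
# windows that do not cross a sequence boundary; `within` optionally restricts
# the scan to candidate start positions
.find_occurrences <- function(b, seqid, codes, within = NULL) {
  k <- length(codes)
  N <- length(b)
  if (N < k) return(integer(0))
  cand <- if (is.null(within)) {
    which(b[seq_len(N - k + 1L)] == codes[1L])
  } else {
    within <- within[within >= 1L & within <= N - k + 1L]
    within[b[within] == codes[1L]]
  }
  for (j in seq_len(k - 1L)) {
    cand <- cand[b[cand + j] == codes[j + 1L]]
  }
  cand[seqid[cand] == seqid[cand + k - 1L]]
}

# draw base codes for given flat positions, using per-position cumulative
# probabilities cum1 <= cum2 <= cum3 (order A, C, G, U)
.draw_bases <- function(idx, cum1, cum2, cum3) {
  u <- runif(length(idx))
  1L + (u > cum1[idx]) + (u > cum2[idx]) + (u > cum3[idx])
}

#' @keywords internal
#' @noRd
.r_utr_sequences <- function(lengths, gc, mods, max_passes = 10L) {
  n <- length(lengths)
  stopifnot(length(gc) == n, nrow(mods) == n,
            identical(colnames(mods), .ALL_MOTIFS),
            all(lengths >= 1L), all(gc >= 0 & gc <= 1), all(mods >= 0))
  lengths <- as.integer(lengths)
  N <- sum(lengths)
  seqid <- rep.int(seq_len(n), lengths)
  pA <- rep.int((1 - gc) / 2, lengths)
  pC <- rep.int(gc / 2, lengths)
  cum1 <- pA
  cum2 <- pA + pC
  cum3 <- cum2 + pC # P(G) = P(C) = gc/2
  b <- .draw_bases(seq_len(N), cum1, cum2, cum3)

  base_prob <- function(code, seqs) {
    # per-sequence probability of one base code
    p <- cbind((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    p[seqs, code]
  }

  # enrichment: plant extra occurrences at rate (s - 1) * neutral expectation
  for (m in colnames(mods)) {
    s <- mods[, m]
    enr <- which(s > 1)
    if (!length(enr)) next
    codes <- .motif_codes(m)
    k <- length(codes)
    pm <- rep(1, length(enr))
    for (cd in codes) pm <- pm * base_prob(cd, enr)
    if (any(pm == 0)) {
      stop("impossible composition: motif ", m, " is enriched in a sequence ",
           "whose base probabilities exclude one of its bases", call. = FALSE)
    }
    lam <- (s[enr] - 1) * lengths[enr] * pm
    n_extra <- rpois(length(enr), lam)
    n_extra <- pmin(n_extra, pmax(lengths[enr] - k + 1L, 0L))
    tot <- sum(n_extra)
    if (tot > 0L) {
      seq_of <- rep.int(enr, n_extra)
      offset <- (cumsum(lengths) - lengths)[seq_of]
      starts <- offset + 1L +
        floor(runif(tot) * (lengths[seq_of] - k + 1L))
      idx <- rep(starts, each = k) + seq_len(k) - 1L
      b[idx] <- rep(codes, times = tot)
    }
  }

  # suppression: thin occurrences toward s * neutral expectation
  for (m in colnames(mods)) {
    s_all <- pmin(mods[, m], 1)
    if (all(s_all == 1)) next
    codes <- .motif_codes(m)
    k <- length(codes)
    to_test <- .find_occurrences(b, seqid, codes)
    for (pass in seq_len(max_passes)) {
      if (!length(to_test)) break
      s <- s_all[seqid[to_test]]
      rej <- to_test[runif(length(to_test)) >= s]
      if (!length(rej)) break
      idx <- rep(rej, each = k) + seq_len(k) - 1L
      b[idx] <- .draw_bases(idx, cum1, cum2, cum3)
      # rescan only windows overlapping the redrawn bases
      nb <- unique(rep(rej, each = 2L * k - 1L) + (-(k - 1L)):(k - 1L))
      to_test <- .find_occurrences(b, seqid, codes, within = nb)
    }
    # hard suppression (s = 0) is a guarantee, not a rate: break any leftover
    # occurrence by replacing its middle base with a different one
    zero_seqs <- which(mods[, m] == 0)
    if (length(zero_seqs)) {
      in_zero <- function(occ) occ[seqid[occ] %in% zero_seqs]
      mid <- as.integer(ceiling(k / 2))
      for (iter in 1:50) {
        occ <- in_zero(.find_occurrences(b, seqid, codes))
        if (!length(occ)) break
        pos <- occ + mid - 1L
        for (tries in 1:30) {
          clash <- pos[b[pos] == codes[mid]]
          if (!length(clash)) break
          b[clash] <- .draw_bases(clash, cum1, cum2, cum3)
        }
        if (length(pos[b[pos] == codes[mid]])) {
          stop("cannot suppress motif ", m, ": sequence composition admits ",
               "no alternative base", call. = FALSE)
        }
      }
      if (length(in_zero(.find_occurrences(b, seqid, codes)))) {
        stop("failed to fully suppress motif ", m, call. = FALSE)
      }
    }
  }

  # realized per-sequence counts of every modified motif
  modified <- colnames(mods)[apply(mods != 1, 2L, any)]
  realized <- NULL
  if (length(modified)) {
    realized <- vapply(modified, function(m) {
      occ <- .find_occurrences(b, seqid, .motif_codes(m))
      tabulate(seqid[occ], nbins = n)
    }, integer(n))
    if (is.null(dim(realized))) realized <- matrix(realized, nrow = n)
    colnames(realized) <- modified
  }

  big <- paste(.RNA_BASES[b], collapse = "")
  ends <- cumsum(lengths)
  seqs <- substring(big, ends - lengths + 1L, ends)
  attr(seqs, "realized_counts") <- realized
  seqs
}

#' Generate one random 5'UTR sequence
#'
#' Bases are drawn iid with `P(G) = P(C) = gc/2` and `P(A) = P(U) =
#' (1 - gc)/2`; motif modifiers then thin (factor below 1) or plant (factor
#' above 1) occurrences of the tracked motifs toward the scaled neutral rate.
#' A factor of exactly 0 guarantees zero occurrences. Uses the current R
#' random-number state; seed externally (e.g. `set.seed()` or
#' `withr::with_seed()`) for reproducibility.
#'
#' @param length Sequence length in nucleotides (>= 1; >= 3 for any
#'   trinucleotide to fit).
#' @param gc Target G+C fraction in `[0, 1]`.
#' @param motif_modifiers Named list of single factors per motif (see
#'   [synthetic_spec()]).
#' @param max_passes Cap on resampling passes.
#' @return An RNA string of exactly `length` characters.
#' @export
#' @examples
#' set.seed(1)
#' generate_sequence(50, gc = 0.6)
#' generate_sequence(50, gc = 0.5, motif_modifiers = list(AUG = 0))
generate_sequence <- function(length, gc, motif_modifiers = list(),
                              max_passes = 10L) {
  stopifnot(length >= 1L, gc >= 0, gc <= 1)
  mods <- matrix(1, 1L, length(.ALL_MOTIFS),
                 dimnames = list(NULL, .ALL_MOTIFS))
  for (m in names(motif_modifiers)) {
    stopifnot(m %in% .ALL_MOTIFS, base::length(motif_modifiers[[m]]) == 1L)
    mods[1L, m] <- motif_modifiers[[m]]
  }
  as.character(.r_utr_sequences(as.integer(length), gc, mods,
                                max_passes = max_passes))
}

#' Generate a synthetic 5'UTR dataset with planted effects
#'
#' Per gene: draws G+C content from the spec's Beta model and per-sequence
#' motif modifiers from their ranges, computes the target
#' `log10 length = beta_0 + sum(beta_k * x_k) + noise`, rounds to an integer
#' length (floored at 3 nt), and emits the configured number of transcripts
#' per gene, each an independently generated sequence with the gene's
#' covariates. All randomness derives from `spec$seed`; the same spec yields
#' a byte-identical dataset.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_dataset` list: `records` (a `utr_records` data
#'   frame), `truth` (per-gene data frame of drawn covariates, the target
#'   log10 length and length; planted beta in the `planted_beta` attribute,
#'   realized per-transcript counts of modified motifs in the
#'   `realized_counts` attribute) and `spec`.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_genes = 50, seed = 42))
#' head(ds$records)
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_genes
    gc <- rbeta(n, spec$gc_shape1, spec$gc_shape2)
    mods <- matrix(1, n, length(.ALL_MOTIFS),
                   dimnames = list(NULL, .ALL_MOTIFS))
    for (m in names(spec$motif_modifiers)) {
      v <- spec$motif_modifiers[[m]]
      mods[, m] <- if (length(v) == 2L) runif(n, v[1L], v[2L]) else v
    }

    covs <- cbind("(Intercept)" = rep(1, n), gc = gc)
    colnames_mods <- paste0("s_", tolower(colnames(mods)))
    covs <- cbind(covs, structure(mods, dimnames = list(NULL, colnames_mods)))
    beta <- spec$planted_beta
    y <- as.vector(covs[, names(beta), drop = FALSE] %*% beta) +
      rnorm(n, 0, spec$noise_sd)
    len_raw <- as.integer(round(10^y))
    if (mean(len_raw < 3L) > 0.01) {
      stop("synthetic spec yields > 1% of lengths below 3 nt; raise the ",
           "intercept or lower the noise", call. = FALSE)
    }
    len <- pmax(3L, len_raw)

    tpg <- spec$transcripts_per_gene
    n_tx <- if (is.null(names(tpg))) {
      rep.int(tpg, n)
    } else {
      sample(as.integer(names(tpg)), n, replace = TRUE,
             prob = as.numeric(tpg))
    }
    gene_idx <- rep.int(seq_len(n), n_tx)
    tx_rank <- unlist(lapply(n_tx, seq_len), use.names = FALSE)

    seqs <- .r_utr_sequences(len[gene_idx], gc[gene_idx],
                             mods[gene_idx, , drop = FALSE],
                             max_passes = spec$max_passes)
    width <- max(5L, nchar(as.character(n)))
    gene_id <- sprintf(paste0("g%0", width, "d"), gene_idx)
    records <- .new_utr_records(
      data.frame(gene_id = gene_id,
                 transcript_id = sprintf("t%d", tx_rank),
                 sequence = as.character(seqs),
                 length = nchar(seqs),
                 stringsAsFactors = FALSE),
      source = sprintf("synthetic(seed=%d)", spec$seed))

    truth <- data.frame(gene_id = sprintf(paste0("g%0", width, "d"),
                                          seq_len(n)),
                        gc = gc,
                        stringsAsFactors = FALSE)
    for (m in names(spec$motif_modifiers)) {
      truth[[paste0("s_", tolower(m))]] <- mods[, m]
    }
    truth$y_target <- y
    truth$target_length <- len
    attr(truth, "planted_beta") <- beta
    attr(truth, "realized_counts") <- attr(seqs, "realized_counts")

    structure(list(records = records, truth = truth, spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic 5'UTR dataset: %d transcript(s) from %d gene(s)\n",
              nrow(x$records), x$spec$n_genes))
  print(x$spec)
  invisible(x)
}

#' Estimate attenuation of planted coefficients
#'
#' Planted coefficients act on generative covariates (the G+C parameter and
#' the motif modifiers), but the regression is fit on features re-measured
#' from the realized sequences, so estimated coefficients converge to
#' attenuated projection values. This measures the per-predictor attenuation
#' factor empirically: it pools `n_replicates` datasets generated from `spec`
#' (with seeds offset from `spec$seed` so the pilot stream never overlaps a
#' study that increments seeds by small steps), runs the measurement pipeline
#' (featurize, zero-OE filter), fits the full model once on the pooled table,
#' and reports `lambda_j = beta_hat_pooled_j / beta_planted_j` for every
#' planted non-intercept covariate. `lambda_j * beta_planted_j` is then the
#' value a per-replicate estimate should be compared against.
#'
#' @param spec A [synthetic_spec()] with at least one non-intercept planted
#'   coefficient.
#' @param n_replicates Number of pooled pilot replicates (default 20).
#' @param predictors Regression predictor set (default the nine composition
#'   features).
#' @return List with `lambda` (named attenuation factors), `reference`
#'   (attenuation-corrected planted coefficients, named by measured feature),
#'   `pooled_fit` (the pooled `utr_ols`) and `n_pooled`.
#' @export
estimate_attenuation <- function(spec, n_replicates = 20L,
                                 predictors = default_predictors()) {
  stopifnot(inherits(spec, "synthetic_spec"), n_replicates >= 1L)
  beta <- spec$planted_beta
  planted <- setdiff(names(beta), "(Intercept)")
  if (!length(planted)) {
    stop("spec plants no non-intercept coefficients", call. = FALSE)
  }
  feature_of <- c(gc = "gc_content",
                  setNames(paste0("oe_", tolower(.ALL_MOTIFS)),
                           paste0("s_", tolower(.ALL_MOTIFS))))
  tables <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    spec_r <- spec
    spec_r$seed <- spec$seed + 100000L + r
    ds <- generate_dataset(spec_r)
    ft <- feature_table(ds$records, include_uorf = FALSE)
    tables[[r]] <- as.data.frame(apply_zero_oe_filter(ft))
  }
  pooled <- do.call(rbind, tables)
  fit <- fit_ols(pooled, predictors)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  lambda <- vapply(planted, function(cv) {
    est[[feature_of[[cv]]]] / beta[[cv]]
  }, numeric(1L))
  reference <- setNames(lambda * beta[planted], feature_of[planted])
  list(lambda = lambda, reference = reference, pooled_fit = fit,
       n_pooled = nrow(pooled))
}

# ---- toy fixture ------------------------------------------------------------

# Hand-verified integer facts about the toy sequences: base counts, overlapping
# motif counts, uORF presence and the zero-trinucleotide-OE tally. Expected
# real-valued features are derived from these integers through the defining
# closed forms (log10 L, (G+C)/L, obs / (L * prod(count/L))), so the expected
# table never touches the package's counting code.
.toy_facts <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene_id sequence               cA cC cG cU oAUG oUGA oUAA oUAG oCG oUG oUU oUA uorf nzero
g01     AUGAUG                  2  0  2  2    2    1    0    0   0   2   0   0    0     2
g02     AUGAAAUAA               6  0  1  2    1    1    1    0   0   1   0   1    1     1
g03     ACGUACGUACGU            3  3  3  3    0    0    0    0   3   0   0   2    0     4
g04     AUGGCUAAGCUAGGCUGACGUG  5  4  8  5    1    1    1    1   1   3   0   2    1     0
g05     CCAUGGCCUAACCUAGGCUGACC 5  9  5  4    1    1    1    1   0   2   0   2    1     0
g06     GGCCGGCCGGCC            0  6  6  0    0    0    0    0   2   0   0   0    0     4
g07     AUGAUGAUGA              4  0  3  3    3    3    0    0   0   3   0   0    0     2
g10     AUGGCUAAGCUAGGCUGACGUG  5  4  8  5    1    1    1    1   1   3   0   2    1     0
")
  tab
}

# expected feature table of the toy fixture, built from .toy_facts()
.toy_expected <- function() {
  facts <- .toy_facts()
  L <- nchar(facts$sequence)
  f <- cbind(A = facts$cA / L, C = facts$cC / L,
             G = facts$cG / L, U = facts$cU / L)
  oe <- function(obs, motif, wins) {
    bases <- strsplit(motif, "", fixed = TRUE)[[1L]]
    e <- wins * apply(f[, bases, drop = FALSE], 1L, prod)
    ifelse(e == 0, 0, obs / e)
  }
  obs_cols <- list(AUG = facts$oAUG, UGA = facts$oUGA, UAA = facts$oUAA,
                   UAG = facts$oUAG, CG = facts$oCG, UG = facts$oUG,
                   UU = facts$oUU, UA = facts$oUA)
  out <- data.frame(gene_id = facts$gene_id,
                    transcript_id = rep("t1", nrow(facts)),
                    length = L,
                    log10_length = log10(L),
                    gc_content = unname(f[, "G"] + f[, "C"]),
                    stringsAsFactors = FALSE)
  for (m in .ALL_MOTIFS) {
    out[[paste0("oe_", tolower(m))]] <- oe(obs_cols[[m]], m, L)
  }
  out$uorf_present <- facts$uorf
  out$n_zero_tri_oe <- facts$nzero
  out
}

#' Write the hand-checked toy fixture
#'
#' Emits a 10-record FASTA of short, hand-designed 5'UTRs together with the
#' expected feature table for the 8 records that survive import and
#' featurization. The FASTA exercises every validation path: an
#' ambiguity-code record (`g08`, contains `N`) that import must drop, a
#' 2 nt record (`g09`) too short for trinucleotide features, lowercase DNA
#' input (`g10`), a sequence with a uORF (`g02`), sequences with 0-4 zero
#' trinucleotide OE ratios, and a uniform-composition sequence (`g03`) whose
#' minimal length for AUG is exactly 64. The expected features were derived
#' by hand from the defining formulas and are independent of the package's
#' counting code.
#'
#' @param dir Directory to write into (created if needed).
#' @return List with `fasta` (path), `expected_tsv` (path) and `expected`
#'   (the expected feature data frame).
#' @export
#' @examples
#' fx <- make_toy_fixture()
#' readLines(fx$fasta, n = 4)
make_toy_fixture <- function(dir = tempfile("utrlen_fixture_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  facts <- .toy_facts()
  headers <- paste0(">", facts$gene_id, "|t1")
  fasta <- character(0)
  for (i in seq_len(nrow(facts))) {
    seq_i <- facts$sequence[i]
    if (facts$gene_id[i] == "g10") {
      # lowercase DNA spelling of the same sequence: import must normalize it
      seq_i <- tolower(chartr("U", "T", seq_i))
    }
    fasta <- c(fasta, headers[i], seq_i)
  }
  # records that import / featurization must drop
  fasta <- append(fasta, c(">g08|t1", "ACGUNACGU", ">g09|t1", "AC"),
                  after = 14L) # after g07, keeping gene-sorted order
  fasta_path <- file.path(dir, "toy_utrs.fasta")
  writeLines(fasta, fasta_path)

  expected <- .toy_expected()
  tsv_path <- file.path(dir, "toy_expected_features.tsv")
  out <- expected
  num <- vapply(out, is.double, logical(1L))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17L,
                                                  scientific = FALSE,
                                                  trim = TRUE))
  write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)

  list(fasta = fasta_path, expected_tsv = tsv_path, expected = expected)
}
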