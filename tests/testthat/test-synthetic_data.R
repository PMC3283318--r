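test_that("generated sequences honour length and composition constraints", {
  withr::with_seed(31, {
    s <- generate_sequence(500, gc = 1)
    expect_equal(nchar(s), 500L)
    expect_match(s, "^[GC]+$")
    s2 <- generate_sequence(500, gc = 0)
    expect_match(s2, "^[AU]+$")
    s3 <- generate_sequence(77, gc = 0.5)
    expect_equal(nchar(s3), 77L)
  })
})

test_that("a zero modifier fully suppresses the motif", {
  withr::with_seed(32, {
    for (i in 1:10) {
      s <- generate_sequence(300, gc = 0.5, motif_modifiers = list(AUG = 0))
      expect_equal(observed_count(s, "AUG"), 0L)
    }
    s <- generate_sequence(400, gc = 0.4, motif_modifiers = list(CG = 0))
    expect_equal(observed_count(s, "CG"), 0L)
  })
})

test_that("enriching a motif whose bases cannot occur is an error", {
  withr::with_seed(33, {
    expect_error(generate_sequence(100, gc = 1,
                                   motif_modifiers = list(AUG = 2)),
                 "impossible composition")
  })
})

test_that("neutral modifiers give mean OE near 1 and iid base composition", {
  withr::with_seed(34, {
    n <- 250L
    seqs <- vapply(seq_len(n), function(i) generate_sequence(500, gc = 0.5),
                   character(1))
    rec <- data.frame(gene_id = sprintf("g%03d", seq_len(n)),
                      transcript_id = "t1", sequence = seqs,
                      stringsAsFactors = FALSE)
    ft <- feature_table(rec, include_uorf = FALSE)
    for (m in unlist(utr_motifs())) {
      expect_lt(abs(mean(ft[[paste0("oe_", tolower(m))]]) - 1), 0.08)
    }
    # chi-square goodness of fit for the base probabilities, per sequence
    pvals <- vapply(seqs[1:60], function(s) {
      counts <- table(factor(strsplit(s, "")[[1]],
                             levels = c("A", "C", "G", "U")))
      suppressWarnings(chisq.test(counts, p = rep(.25, 4))$p.value)
    }, numeric(1))
    expect_gt(mean(pvals > 0.01), 0.9)
  })
})

test_that("suppression scales occurrence rates toward s x neutral", {
  withr::with_seed(35, {
    count_mean <- function(s_aug) {
      seqs <- vapply(1:150, function(i)
        generate_sequence(400, gc = 0.5,
                          motif_modifiers = list(AUG = s_aug)), character(1))
      mean(vapply(seqs, observed_count, integer(1), motif = "AUG"))
    }
    neutral <- count_mean(1)
    halved <- count_mean(0.5)
    expect_equal(neutral, 400 / 64, tolerance = 0.15)
    expect_equal(halved / neutral, 0.5, tolerance = 0.25)
    enriched <- count_mean(2)
    expect_gt(enriched / neutral, 1.5)
  })
})

test_that("same spec and seed give a byte-identical FASTA", {
  sp <- synthetic_spec(n_genes = 60, seed = 99,
                       motif_modifiers = list(AUG = c(0.3, 1)),
                       planted_beta = c("(Intercept)" = 2.3, gc = 1,
                                        s_aug = -0.5))
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_utr_fasta(generate_dataset(sp)$records, f1)
  write_utr_fasta(generate_dataset(sp)$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed gives a different one
  sp2 <- sp
  sp2$seed <- 100L
  f3 <- tempfile(fileext = ".fasta")
  write_utr_fasta(generate_dataset(sp2)$records, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("transcripts-per-gene model expands genes as configured", {
  sp <- synthetic_spec(n_genes = 30, seed = 5,
                       transcripts_per_gene = c("1" = .5, "3" = .5))
  ds <- generate_dataset(sp)
  per_gene <- table(ds$records$gene_id)
  expect_true(all(per_gene %in% c(1L, 3L)))
  expect_equal(length(per_gene), 30L)
  sp2 <- synthetic_spec(n_genes = 10, seed = 5, transcripts_per_gene = 2L)
  expect_equal(nrow(generate_dataset(sp2)$records), 20L)
})

test_that("measured features track the generative covariates", {
  sp <- synthetic_spec(n_genes = 800, seed = 123,
                       motif_modifiers = list(AUG = c(0.3, 1)),
                       planted_beta = c("(Intercept)" = 2.4, gc = 1,
                                        s_aug = -0.5))
  ds <- generate_dataset(sp)
  ft <- feature_table(ds$records, include_uorf = FALSE)
  merged <- merge(ft, ds$truth, by = "gene_id")
  expect_gt(cor(merged$gc_content, merged$gc), 0.9)
  expect_gt(cor(merged$oe_aug, merged$s_aug), 0.3)
  # realized counts of the modified motif were recorded
  rc <- attr(ds$truth, "realized_counts")
  expect_equal(colnames(rc), "AUG")
  expect_equal(nrow(rc), 800L)
})

test_that("a spec that mostly yields sub-3nt lengths is rejected", {
  sp <- synthetic_spec(n_genes = 200, seed = 1,
                       planted_beta = c("(Intercept)" = 0.1),
                       noise_sd = 0.1)
  expect_error(generate_dataset(sp), "below 3 nt")
})

test_that("null generation: generative covariates do not predict length", {
  # with planted_beta = 0 the response is independent of the drawn covariates
  # by construction, so a regression of measured log10 length on them is null
  mods <- setNames(rep(list(c(0.3, 1)), 8), unlist(utr_motifs()))
  sp <- synthetic_spec(n_genes = 1200, seed = 77, motif_modifiers = mods)
  ds <- generate_dataset(sp)
  ft <- feature_table(ds$records, include_uorf = FALSE)
  d <- merge(ds$truth, ft[, c("gene_id", "log10_length")], by = "gene_id")
  covs <- c("gc", paste0("s_", tolower(unlist(utr_motifs()))))
  fit <- fit_ols(d, covs)
  cf <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  expect_gt(mean(abs(cf$estimate) <= 2 * cf$std_error), 0.6)
  expect_lt(fit$r2, 0.02)
})

test_that("measured OE features carry a finite-length bias under the null", {
  # the documented caveat: even with nothing planted, OE ratios measured from
  # realized sequences associate with length (O(1/L) measurement bias,
  # amplified by the zero-OE filter's length-conditional truncation), so a
  # feature-level regression on a null dataset is NOT expected to be null
  sp <- synthetic_spec(n_genes = 1500, seed = 78)
  ds <- generate_dataset(sp)
  ft <- feature_table(ds$records, include_uorf = FALSE)
  unfiltered <- fit_ols(ft, default_predictors())
  filtered <- fit_ols(apply_zero_oe_filter(ft), default_predictors())
  expect_gt(unfiltered$r2, 0.005) # bias is detectable ...
  expect_gt(filtered$r2, unfiltered$r2) # ... and the filter amplifies it
  expect_lt(filtered$r2, 0.2) # but stays far below planted-effect levels
})

test_that("the toy fixture writes valid files with frozen expectations", {
  fx <- make_toy_fixture()
  expect_true(file.exists(fx$fasta))
  expect_true(file.exists(fx$expected_tsv))
  exp <- fx$expected
  expect_equal(exp$oe_aug[exp$gene_id == "g01"], 9, tolerance = 1e-12)
  expect_equal(exp$uorf_present[exp$gene_id == "g02"], 1L)
  expect_equal(exp$n_zero_tri_oe[exp$gene_id == "g01"], 2L)
  # uniform-composition record: minimal length for AUG is 64
  expect_equal(minimal_length(nucleotide_frequencies("ACGUACGUACGU"), "AUG"),
               64)
  # the expected TSV reparses to the frozen values
  reread <- read.delim(fx$expected_tsv, stringsAsFactors = FALSE)
  expect_equal(reread$oe_uaa, exp$oe_uaa, tolerance = 1e-15)
})

test_that("attenuation estimation returns usable factors for planted terms", {
  sp <- synthetic_spec(n_genes = 400, seed = 9,
                       motif_modifiers = list(AUG = c(0.3, 1)),
                       planted_beta = c("(Intercept)" = 2.5, gc = 1.5,
                                        s_aug = -1))
  att <- estimate_attenuation(sp, n_replicates = 3)
  expect_named(att$lambda, c("gc", "s_aug"))
  expect_named(att$reference, c("gc_content", "oe_aug"))
  # attenuation shrinks, it does not flip or amplify
  expect_true(all(att$lambda > 0 & att$lambda <= 1.2))
  expect_equal(att$reference[["gc_content"]], att$lambda[["gc"]] * 1.5)
})
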