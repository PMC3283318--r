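#' Configuration of an end-to-end 5'UTR length analysis
#'
#' Collects every option of [run_pipeline()] with defaults matching the
#' package's reference analysis choices: zero-OE filtering, `L`-window
#' expected counts, unadjusted-R-squared RCVE, partial correlations on the
#' selected predictor set, and backward elimination at `alpha = 0.05`. The
#' resolved configuration is echoed verbatim into the run's JSON summary so a
#' run can be reproduced from its report alone.
#'
#' @param input Path to a FASTA file of 5'UTRs, or `NULL` to analyse a
#'   synthetic dataset.
#' @param synthetic_spec A [synthetic_spec()] used when `input` is `NULL`.
#' @param rule [header_rule()] for FASTA headers.
#' @param predictors Candidate predictor columns (default the nine
#'   composition features; see [default_predictors()]).
#' @param response Response column (default `"log10_length"`).
#' @param alpha Backward-elimination significance threshold.
#' @param filter `"zero_oe"` (default) or `"length"`.
#' @param max_zero_oe Tolerated zero trinucleotide OE ratios (zero-OE rule).
#' @param min_length Length threshold (length rule).
#' @param oe_convention Expected-count convention, see [expected_count()].
#' @param rcve_r2 R-squared convention for RCVE, see [rcve()].
#' @param partial_set Compute partial correlations over the `"selected"`
#'   predictors (default) or over `"all"` candidates.
#' @param include_uorf Compute the uORF presence feature.
#' @param seed Seed for the transcript draw (and recorded provenance).
#' @param out_dir Output directory; a fresh temporary directory by default.
#' @return A `utr_run_config` object.
#' @export
run_config <- function(input = NULL,
                       synthetic_spec = NULL,
                       rule = header_rule(),
                       predictors = default_predictors(),
                       response = "log10_length",
                       alpha = 0.05,
                       filter = c("zero_oe", "length"),
                       max_zero_oe = 1L,
                       min_length = 30L,
                       oe_convention = c("length", "windows"),
                       rcve_r2 = c("unadjusted", "adjusted"),
                       partial_set = c("selected", "all"),
                       include_uorf = TRUE,
                       seed = 1L,
                       out_dir = NULL) {
  if (is.null(input) && is.null(synthetic_spec)) {
    stop("provide either an input FASTA path or a synthetic_spec",
         call. = FALSE)
  }
  if (!is.null(synthetic_spec)) {
    stopifnot(inherits(synthetic_spec, "synthetic_spec"))
  }
  structure(list(input = input,
                 synthetic_spec = synthetic_spec,
                 rule = rule,
                 predictors = predictors,
                 response = response,
                 alpha = alpha,
                 filter = match.arg(filter),
                 max_zero_oe = as.integer(max_zero_oe),
                 min_length = as.integer(min_length),
                 oe_convention = match.arg(oe_convention),
                 rcve_r2 = match.arg(rcve_r2),
                 partial_set = match.arg(partial_set),
                 include_uorf = isTRUE(include_uorf),
                 seed = as.integer(seed),
                 out_dir = out_dir),
            class = "utr_run_config")
}

# JSON-serializable echo of a config
.config_echo <- function(config) {
  echo <- unclass(config)
  echo$rule <- unclass(config$rule)
  if (!is.null(config$synthetic_spec)) {
    sp <- unclass(config$synthetic_spec)
    sp$planted_beta <- as.list(sp$planted_beta)
    sp$transcripts_per_gene <- if (is.null(names(sp$transcripts_per_gene))) {
      sp$transcripts_per_gene
    } else {
      as.list(sp$transcripts_per_gene)
    }
    echo$synthetic_spec <- sp
  }
  echo
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full 5'UTR length analysis
#'
#' Executes, in order: sequence import (or synthetic generation), one
#' transcript per gene, feature computation, filtering, the full regression
#' with VIF screen, backward elimination, partial correlations and RCVE, and
#' writes every report into the output directory:
#' `features.tsv`, `filter_report.tsv`, `model_coefficients.tsv` (one row
#' per candidate, `ns` for eliminated predictors, adjusted R-squared footer),
#' `partial_correlations.tsv`, `vif.tsv`, `rcve.tsv`,
#' `selection_trace.tsv` and a machine-readable `summary.json`. When the
#' filtered table is too small to support the regression, the modelling
#' stages are skipped and the reason recorded in the summary. A stage failure
#' writes a `FAILED` marker file naming the stage before the error
#' propagates.
#'
#' @param config A [run_config()].
#' @return A `utr_run_report` list with the feature tables, fitted models,
#'   importance statistics, per-stage counts and the output paths, invisibly.
#' @export
#' @examples
#' cfg <- run_config(synthetic_spec = synthetic_spec(n_genes = 300, seed = 3),
#'                   include_uorf = FALSE)
#' report <- run_pipeline(cfg)
#' report$summary$n_retained
run_pipeline <- function(config) {
  stopifnot(inherits(config, "utr_run_config"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("utrlen_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- "setup"
  fail_marker <- function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage,
                       conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  t_start <- proc.time()[["elapsed"]]
  timing <- list()
  tick <- function() {
    now <- proc.time()[["elapsed"]]
    elapsed <- now - t_start
    t_start <<- now
    elapsed
  }

  withCallingHandlers(
    tryCatch({
      # -- load -------------------------------------------------------------
      stage <- "load"
      if (!is.null(config$input)) {
        records <- read_utr_fasta(config$input, config$rule)
        truth <- NULL
      } else {
        ds <- generate_dataset(config$synthetic_spec)
        records <- ds$records
        truth <- ds$truth
      }
      n_input <- nrow(records) + nrow(drop_report(records))
      n_io_dropped <- nrow(drop_report(records))
      timing$load <- tick()

      # -- transcript selection ---------------------------------------------
      stage <- "select_transcript"
      selected <- select_one_transcript_per_gene(records, config$seed)
      n_tx_dropped <- attr(selected, "n_transcripts_dropped")
      timing$select_transcript <- tick()

      # -- featurize ---------------------------------------------------------
      stage <- "featurize"
      ft <- feature_table(selected, convention = config$oe_convention,
                          include_uorf = config$include_uorf)
      n_short_dropped <- attr(ft, "provenance")$n_short_dropped
      .write_tsv(drop_report(records), file.path(out_dir, "drop_report.tsv"))
      write_feature_table(ft, file.path(out_dir, "features.tsv"))
      timing$featurize <- tick()

      # -- filter -------------------------------------------------------------
      stage <- "filter"
      filtered <- switch(config$filter,
                         zero_oe = apply_zero_oe_filter(ft,
                                                        config$max_zero_oe),
                         length = apply_length_filter(ft,
                                                      config$min_length))
      .write_tsv(filter_report(filtered),
                 file.path(out_dir, "filter_report.tsv"))
      n_filter_dropped <- filter_report(filtered)$removed
      length_report <- length_distribution_report(filtered)
      .write_tsv(length_report$quantiles,
                 file.path(out_dir, "length_quantiles.tsv"))
      timing$filter <- tick()

      # -- model --------------------------------------------------------------
      stage <- "model"
      preds <- config$predictors
      model <- NULL
      model_note <- NULL
      if (nrow(filtered) < length(preds) + 3L) {
        model_note <- sprintf(
          "modelling skipped: %d filtered row(s) cannot support %d predictors",
          nrow(filtered), length(preds))
      } else {
        full <- fit_ols(filtered, preds, config$response)
        vifs <- if (length(preds) >= 2L) vif(filtered, preds) else NULL
        sel <- backward_select(filtered, preds, config$response,
                               alpha = config$alpha)
        partial_on <- switch(config$partial_set,
                             selected = sel$trace$final_predictors,
                             all = preds)
        partials <- if (length(partial_on)) {
          partial_correlations(filtered, partial_on, config$response)
        } else {
          setNames(numeric(0), character(0))
        }
        rcves <- tryCatch(rcve(filtered, preds, config$response,
                               r2_type = config$rcve_r2),
                          error = function(e) {
                            model_note <<- conditionMessage(e)
                            NULL
                          })
        model <- list(full = full, vif = vifs, selection = sel,
                      partial_correlations = partials, rcve = rcves)

        # Table-1-shaped coefficient report: one row per candidate, ns when
        # eliminated, adjusted R^2 footer
        est <- setNames(sel$fit$coefficients$estimate,
                        sel$fit$coefficients$term)
        pv <- setNames(sel$fit$coefficients$p_value,
                       sel$fit$coefficients$term)
        in_final <- preds %in% sel$trace$final_predictors
        coef_tab <- data.frame(
          predictor = c("(Intercept)", preds, "adjusted_R2"),
          coefficient = c(
            format(est[["(Intercept)"]], digits = 10L),
            ifelse(in_final,
                   vapply(preds, function(p)
                     if (p %in% names(est))
                       format(est[[p]], digits = 10L) else "ns", ""),
                   "ns"),
            format(sel$fit$adj_r2, digits = 10L)),
          p_value = c(format(pv[["(Intercept)"]], digits = 6L),
                      ifelse(in_final,
                             vapply(preds, function(p)
                               if (p %in% names(pv))
                                 format(pv[[p]], digits = 6L) else "ns", ""),
                             "ns"),
                      ""),
          stringsAsFactors = FALSE)
        .write_tsv(coef_tab, file.path(out_dir, "model_coefficients.tsv"))

        partial_tab <- data.frame(
          predictor = preds,
          partial_correlation = vapply(preds, function(p)
            if (p %in% names(partials))
              format(partials[[p]], digits = 10L) else "ns", ""),
          stringsAsFactors = FALSE)
        .write_tsv(partial_tab,
                   file.path(out_dir, "partial_correlations.tsv"))

        if (!is.null(vifs)) {
          .write_tsv(data.frame(predictor = names(vifs),
                                vif = unname(vifs),
                                flagged = names(vifs) %in%
                                  attr(vifs, "flagged")),
                     file.path(out_dir, "vif.tsv"))
        }
        if (!is.null(rcves)) {
          .write_tsv(data.frame(predictor = names(rcves),
                                rcve = unname(rcves)),
                     file.path(out_dir, "rcve.tsv"))
        }
        .write_tsv(sel$trace$steps,
                   file.path(out_dir, "selection_trace.tsv"))
      }
      timing$model <- tick()

      # -- summary -------------------------------------------------------------
      stage <- "summary"
      summary <- list(
        n_input = n_input,
        n_io_dropped = n_io_dropped,
        n_transcript_dropped = n_tx_dropped,
        n_short_dropped = n_short_dropped,
        n_filter_dropped = n_filter_dropped,
        n_retained = nrow(filtered),
        filter_rule = config$filter,
        median_length = unname(quantile(filtered$length, 0.5)),
        log10_length_normality_r = length_report$normality_r,
        selected_predictors = if (is.null(model)) NULL else
          as.list(model$selection$trace$final_predictors),
        adjusted_r2 = if (is.null(model)) NULL else
          model$selection$fit$adj_r2,
        max_vif = if (is.null(model) || is.null(model$vif)) NULL else
          max(model$vif),
        model_note = model_note,
        alpha = config$alpha,
        seed = config$seed,
        config = .config_echo(config),
        timings_sec = timing
      )
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)

      report <- list(records = records,
                     selected = selected,
                     features = ft,
                     filtered = filtered,
                     length_report = length_report,
                     model = model,
                     truth = truth,
                     summary = summary,
                     out_dir = out_dir)
      class(report) <- "utr_run_report"
      invisible(report)
    }, error = fail_marker),
    warning = function(w) {
      message(sprintf("[%s] %s", stage, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
}

#' @export
print.utr_run_report <- function(x, ...) {
  s <- x$summary
  cat("5'UTR length analysis run\n")
  cat(sprintf("  input records: %d (io dropped %d, extra transcripts %d, short %d)\n",
              s$n_input, s$n_io_dropped, s$n_transcript_dropped,
              s$n_short_dropped))
  cat(sprintf("  filter (%s): %d removed, %d retained\n", s$filter_rule,
              s$n_filter_dropped, s$n_retained))
  if (!is.null(s$model_note)) {
    cat("  note:", s$model_note, "\n")
  }
  if (!is.null(x$model)) {
    cat(sprintf("  selected predictors: %s\n",
                if (length(s$selected_predictors))
                  paste(unlist(s$selected_predictors), collapse = ", ")
                else "(intercept only)"))
    cat(sprintf("  adjusted R^2 = %.4f\n", s$adjusted_r2))
  }
  cat("  outputs in:", x$out_dir, "\n")
  invisible(x)
}
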