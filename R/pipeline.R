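#' Pipeline configuration
#'
#' Bundles every stage's settings: simulation, band definitions, statistics
#' (alpha, Holm flag), decoder model and cross-validation, the design
#' dimensions to process, and the global seed from which all stage seeds
#' are derived.
#'
#' @param sim A [sim_config()].
#' @param bands Band definition tibble ([default_bands()]).
#' @param alpha Significance level for the band comparisons.
#' @param holm Use Holm-adjusted p-values for the significance flags.
#' @param model A [model_config()].
#' @param k Cross-validation repeats per dimension.
#' @param vdeps Design dimensions to process (non-empty subset of the
#'   four).
#' @param group_split Participant-wise CV splits (see [crossval()]).
#' @param balance `"seconds"` balances epoch-yielding seconds (default,
#'   guarantees exactly balanced epoch sets); `"tags"` balances the
#'   resolved timeline before extraction.
#' @param seed Global integer seed.
#' @param out_dir Directory for stage artifacts, or `NULL` to skip
#'   writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), bands = default_bands(),
                            alpha = 0.05, holm = FALSE,
                            model = model_config(), k = 10L,
                            vdeps = VDEPS, group_split = FALSE,
                            balance = c("seconds", "tags"),
                            seed = 1L, out_dir = NULL) {
  if (length(vdeps) == 0L) stopf("vdeps must name at least one design dimension")
  bad <- setdiff(vdeps, VDEPS)
  if (length(bad)) stopf("unknown design dimension(s): %s",
                         paste(bad, collapse = ", "))
  structure(list(
    sim = sim, bands = validate_bands(bands, sim$fs), alpha = alpha,
    holm = holm, model = model, k = assert_count(k, "k", min = 2L),
    vdeps = vdeps, group_split = isTRUE(group_split),
    balance = match.arg(balance),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `sim`, `model`
#' and `bands` are nested maps passed to their constructors.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  model <- do.call(model_config, y$model %||% list())
  bands <- if (is.null(y$bands)) default_bands() else {
    do.call(rbind, lapply(y$bands, tibble::as_tibble))
  }
  pipeline_config(
    sim = sim, bands = bands, alpha = y$alpha %||% 0.05,
    holm = isTRUE(y$holm), model = model, k = y$k %||% 10L,
    vdeps = unlist(y$vdeps) %||% VDEPS,
    group_split = isTRUE(y$group_split),
    balance = y$balance %||% "seconds",
    seed = y$seed %||% 1L, out_dir = y$out_dir
  )
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2L)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Simulates recordings and two-expert annotations, resolves them, and for
#' each requested design dimension: builds intervals, extracts epochs,
#' computes band powers and the class comparison, then balances,
#' normalizes, spatially re-orders and cross-validates the convolutional
#' decoder. A failing dimension is recorded and the others continue.
#'
#' @param cfg A [pipeline_config()].
#' @return A `run_report`: list with `counts` (class-count summary),
#'   `results` (per-dimension `stats`, `cv`, `n_epochs` or `error`),
#'   `config_hash`, `elapsed_s`, `version`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  sim <- cfg$sim
  sim$seed <- derive_seed(cfg$seed, 11L)
  out <- cfg$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  truth <- make_truth(sim)
  rec <- make_recordings(sim, truth)
  tags <- make_expert_tags(sim, truth)
  resolved <- resolve_tags(tags[[1]], tags[[2]])
  counts <- count_classes(resolved)
  if (!is.null(out)) {
    write_annotations(tags, file.path(out, "annotations.csv"))
    utils::write.csv(counts, file.path(out, "class_counts.csv"),
                     row.names = FALSE)
  }

  results <- list()
  for (vd in cfg$vdeps) {
    results[[vd]] <- tryCatch({
      src <- if (cfg$balance == "tags") {
        balance_seconds(resolved, vd, seed = derive_seed(cfg$seed, 21L))
      } else {
        resolved
      }
      iv <- build_intervals(src, vd)
      es <- extract_epochs(rec, iv, n_channels_eeg = sim$n_channels_eeg)
      if (length(es) == 0L) stopf("no epochs extracted for '%s'", vd)

      bp <- band_power_table(es, cfg$bands)
      stats_rep <- compare_vdep_bands(bp, vd, alpha = cfg$alpha,
                                      holm = cfg$holm)
      if (!is.null(out)) {
        export_band_table(bp, file.path(out, paste0("bands_", vd, ".csv")))
        utils::write.csv(stats_rep, file.path(out, paste0("stats_", vd, ".csv")),
                         row.names = FALSE)
        utils::write.csv(violin_data(bp),
                         file.path(out, paste0("violin_", vd, ".csv")),
                         row.names = FALSE)
      }

      balanced <- if (cfg$balance == "seconds") {
        balance_epochs(es, seed = derive_seed(cfg$seed, 22L))
      } else {
        es
      }
      dec <- normalize_epochs(spatial_reorder(balanced))
      cv <- crossval(dec, k = cfg$k, cfg = cfg$model,
                     seed = derive_seed(cfg$seed, 23L),
                     group_split = cfg$group_split)
      if (!is.null(out)) {
        utils::write.csv(cv$folds, file.path(out, paste0("cv_", vd, ".csv")),
                         row.names = FALSE)
        jsonlite::write_json(
          list(vdep = vd, folds = cv$folds, means = as.list(cv$means)),
          file.path(out, paste0("cv_", vd, ".json")),
          auto_unbox = TRUE, digits = NA
        )
      }
      list(stats = stats_rep, cv = cv, n_epochs = length(balanced))
    }, error = function(e) {
      warning(sprintf("dimension '%s' failed: %s", vd, conditionMessage(e)),
              call. = FALSE)
      list(error = conditionMessage(e))
    })
  }

  report <- structure(list(
    counts = counts,
    results = results,
    config_hash = config_hash(cfg),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    version = as.character(utils::packageVersion("vdepeeg"))
  ), class = "run_report")
  if (!is.null(out)) write_report(report, out)
  report
}

write_report <- function(report, out) {
  ok <- names(report$results)[!vapply(report$results, function(r)
    !is.null(r$error), logical(1))]
  lines <- c(
    "# Pipeline run report", "",
    sprintf("- config hash: %s", report$config_hash),
    sprintf("- package version: %s", report$version),
    sprintf("- elapsed: %.1f s", report$elapsed_s),
    "", "## Class counts", "",
    utils::capture.output(print(as.data.frame(report$counts))),
    ""
  )
  for (vd in names(report$results)) {
    r <- report$results[[vd]]
    lines <- c(lines, sprintf("## %s", vd), "")
    if (!is.null(r$error)) {
      lines <- c(lines, sprintf("FAILED: %s", r$error), "")
    } else {
      lines <- c(lines,
                 utils::capture.output(print(as.data.frame(r$stats))),
                 "",
                 sprintf("Decoder (%d epochs): mean AUC %.4f, accuracy %.4f, PR-AUC %.4f",
                         r$n_epochs, r$cv$means[["auc"]],
                         r$cv$means[["accuracy"]], r$cv$means[["pr_auc"]]),
                 "")
    }
  }
  writeLines(lines, file.path(out, "report.md"))
  slim <- list(
    config_hash = report$config_hash, version = report$version,
    counts = report$counts,
    results = lapply(report$results, function(r) {
      if (!is.null(r$error)) list(error = r$error) else
        list(stats = r$stats, cv_means = as.list(r$cv$means),
             cv_folds = r$cv$folds, n_epochs = r$n_epochs)
    })
  )
  jsonlite::write_json(slim, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$counts)
  for (vd in names(x$results)) {
    r <- x$results[[vd]]
    if (!is.null(r$error)) {
      cat(sprintf("  %s: FAILED (%s)\n", vd, r$error))
    } else {
      cat(sprintf("  %s: %d epochs; %d/5 bands significant; mean AUC %.3f\n",
                  vd, r$n_epochs, sum(r$stats$significant),
                  r$cv$means[["auc"]]))
    }
  }
  invisible(x)
}
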