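#' Read / write count matrices and sample tables
#'
#' Counts are TSV with genes as rows (first column `gene`) and one column
#' per sample; the sample table is TSV with columns `sample_id`, `diet`,
#' `tissue`, `replicate`, `batch`. Lines starting with `#` are treated
#' as comments. Readers validate: unique ids, integer non-negative
#' counts.
#'
#' @param path file path.
#' @param counts genes x samples matrix.
#' @param meta sample tibble.
#' @return `read_counts()`: integer matrix with gene rownames;
#'   `read_meta()`: tibble.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (names(df)[1] != "gene") {
    stop("counts TSV must have a leading `gene` column", call. = FALSE)
  }
  if (anyDuplicated(df$gene)) stop("duplicate gene ids", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene
  m
}

#' @rdname read_counts
#' @export
read_meta <- function(path) {
  meta <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  need <- c("sample_id", "diet", "tissue", "replicate", "batch")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  meta[need]
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  df <- tibble::as_tibble(counts, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname read_counts
#' @export
write_meta <- function(meta, path) {
  readr::write_tsv(meta, path)
  invisible(path)
}

#' Check that a count matrix and a sample table describe the same samples
#'
#' @param counts genes x samples matrix.
#' @param meta sample tibble.
#' @return invisibly TRUE; errors naming the offending samples.
#' @export
validate_counts_meta <- function(counts, meta) {
  only_counts <- setdiff(colnames(counts), meta$sample_id)
  only_meta <- setdiff(meta$sample_id, colnames(counts))
  if (length(only_counts) || length(only_meta)) {
    stop("sample mismatch; only in counts: [",
         paste(only_counts, collapse = ", "), "], only in metadata: [",
         paste(only_meta, collapse = ", "), "]", call. = FALSE)
  }
  invisible(TRUE)
}

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    simulate = list(enabled = TRUE, n_genes = 2000, n_replicates = 6,
                    pi_de = 0.2, effect_size_sd = 0.5, rho_concord = 0.75,
                    dispersion = 0.05, module_spec = list()),
    preprocess = list(min_count = 10, min_samples = 2, var_threshold = 1.0,
                      pseudocount = 1),
    de = list(alpha = 0.05, pseudocount = 0.5),
    concordance = list(n_perm = 100, per_pseudo = 2, gene_set = "all"),
    network = list(power = 23, cut_height = 0.95, min_size = 30,
                   merge_threshold = 0.9, resamples = 100, kept = 4,
                   match_fraction = 0.10, support_fraction = 0.50),
    genesets = list(mode = "ttest", min_size = 10, gmt = NULL,
                    n_synthetic_sets = 25)
  )
}

#' Pipeline configuration with strict validation
#'
#' Nested configuration mirroring each stage's parameters; defaults are
#' the conventional settings for this design (power 23, minimum module size 30, 100
#' permutations, 100 resamples, FDR 0.05). Unknown keys at either level
#' are rejected before any computation.
#'
#' @param ... named overrides: either top-level keys (`seed`) or named
#'   lists per section, e.g. `simulate = list(n_genes = 500)`.
#' @return a validated nested list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(seed = 7, simulate = list(n_genes = 200))
#' @export
pipeline_config <- function(...) {
  defaults <- .pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (section in names(over)) {
    if (is.list(defaults[[section]])) {
      if (!is.list(over[[section]])) {
        stop("section `", section, "` must be a named list", call. = FALSE)
      }
      bad <- setdiff(names(over[[section]]), names(defaults[[section]]))
      if (length(bad) > 0) {
        stop("unknown key(s) in `", section, "`: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      defaults[[section]][names(over[[section]])] <- over[[section]]
    } else {
      defaults[[section]] <- over[[section]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

# Per-stage seed derived deterministically from the global seed and the
# stage name, so stages are independently reproducible.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

.stamp_tsv <- function(x, path, run_id) {
  writeLines(sprintf("# dietseq %s run %s",
                     as.character(packageVersion("dietseq")), run_id),
             path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> preprocess -> differential
#' expression -> per-tissue concordance -> co-expression modules (with
#' resampling robustness and eigengene ANOVA) -> gene-set analysis,
#' writing stage outputs as TSV (each with a version/run-id comment
#' header) and a JSON run manifest recording the config, per-stage seeds
#' and output digests. Any stage error aborts the run after writing a
#' partial manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param counts,meta input data when `config$simulate$enabled` is
#'   FALSE.
#' @return invisibly, a list with the per-stage results and the manifest.
#' @export
run_all <- function(config, out_dir, counts = NULL, meta = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seeds <- list()
  stage_seed <- function(stage) {
    seeds[[stage]] <<- derive_seed(config$seed, stage)
    seeds[[stage]]
  }
  run_id <- substr(tools::md5sum(
    {f <- tempfile(); writeLines(jsonlite::toJSON(
      unclass(config), auto_unbox = TRUE, null = "null", force = TRUE), f); f}
  ), 1, 8)
  names(run_id) <- NULL

  manifest <- list(
    tool = "dietseq", version = as.character(packageVersion("dietseq")),
    run_id = run_id, config = unclass(config), seeds = list(),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), status = "running"
  )
  write_manifest <- function() {
    manifest$seeds <- seeds
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", force = TRUE,
                         pretty = TRUE)
  }
  fail <- function(stage, e) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    write_manifest()
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }

  results <- list()

  if (isTRUE(config$simulate$enabled)) {
    stage("simulate", {
      sc <- do.call(sim_config, c(
        config$simulate[setdiff(names(config$simulate), "enabled")],
        list(seed = stage_seed("simulate"))))
      sim <- simulate_counts(sc)
      counts <- sim$counts
      meta <- sim$meta
      write_truth(sim$truth, file.path(out_dir, "truth"))
      results$sim <- sim
    })
  } else if (is.null(counts) || is.null(meta)) {
    stop("provide `counts` and `meta` when simulation is disabled",
         call. = FALSE)
  }
  validate_counts_meta(counts, meta)
  .stamp_tsv(tibble::as_tibble(counts, rownames = "gene"),
             file.path(out_dir, "counts.tsv"), run_id)
  .stamp_tsv(meta, file.path(out_dir, "meta.tsv"), run_id)

  pp <- config$preprocess
  stage("preprocess", {
    n0 <- nrow(counts)
    counts_v <- filter_low_variance(counts, threshold = pp$var_threshold)
    n1 <- nrow(counts_v)
    counts_f <- filter_low_counts(counts_v, min_count = pp$min_count,
                                  min_samples = pp$min_samples)
    n2 <- nrow(counts_f)
    message(sprintf("filters: %d -> %d (variance >= %g) -> %d (counts)",
                    n0, n1, pp$var_threshold, n2))
    sf <- estimate_size_factors(counts_f)
    expr <- shifted_log_transform(counts_f, sf,
                                  pseudocount = pp$pseudocount)
    di <- estimate_surrogate_variable(expr, meta)
    corrected <- remove_batch_effects(expr, di)
    results$preprocess <- list(
      counts = counts_f, size_factors = sf, expr = expr,
      design_info = di, corrected = corrected,
      filter_log = tibble::tibble(
        step = c("input", "variance_filter", "count_filter"),
        n_genes = c(n0, n1, n2)))
    .stamp_tsv(tibble::tibble(sample_id = names(sf), size_factor = sf),
               file.path(out_dir, "size_factors.tsv"), run_id)
    .stamp_tsv(tibble::tibble(sample_id = names(di$sv), sv = di$sv),
               file.path(out_dir, "surrogate_variable.tsv"), run_id)
    .stamp_tsv(tibble::as_tibble(corrected, rownames = "gene"),
               file.path(out_dir, "expr_corrected.tsv"), run_id)
    .stamp_tsv(results$preprocess$filter_log,
               file.path(out_dir, "filter_log.tsv"), run_id)
  })

  stage("de", {
    de <- run_de(results$preprocess$counts, meta,
                 sv = results$preprocess$design_info,
                 alpha = config$de$alpha,
                 pseudocount = config$de$pseudocount)
    results$de <- de
    .stamp_tsv(de$results, file.path(out_dir, "de_results.tsv"), run_id)
    .stamp_tsv(de$fold_changes, file.path(out_dir, "fold_changes.tsv"),
               run_id)
  })

  stage("concordance", {
    cc <- config$concordance
    gene_subset <- NULL
    if (identical(cc$gene_set, "de")) {
      sig <- results$de$results |>
        dplyr::filter(.data$contrast == "treatment",
                      !is.na(.data$p_adj),
                      .data$p_adj < config$de$alpha)
      gene_subset <- sig$gene
    }
    conc <- purrr::map(unique(meta$tissue), function(t) {
      run_concordance(results$preprocess$counts, meta, tissue = t,
                      n_perm = cc$n_perm, per_pseudo = cc$per_pseudo,
                      seed = stage_seed(paste0("concordance_", t)),
                      pseudocount = config$de$pseudocount,
                      genes = gene_subset)
    })
    results$concordance <- conc
    .stamp_tsv(dplyr::bind_rows(lapply(conc, `[[`, "stats")),
               file.path(out_dir, "concordance.tsv"), run_id)
  })

  stage("modules", {
    nw <- config$network
    fit <- detect_modules(results$preprocess$corrected, power = nw$power,
                          cut_height = nw$cut_height,
                          min_size = nw$min_size,
                          merge_threshold = nw$merge_threshold)
    rob <- resample_robustness(results$preprocess$corrected, meta, fit,
                               resamples = nw$resamples, kept = nw$kept,
                               match_fraction = nw$match_fraction,
                               support_threshold = nw$support_fraction,
                               seed = stage_seed("modules"))
    anova_tab <- if (nrow(fit$eigengenes) > 0) {
      eigengene_anova(fit, meta)
    } else {
      tibble::tibble(module = character(0), term = character(0),
                     df = numeric(0), statistic = numeric(0),
                     p = numeric(0), p_adj = numeric(0))
    }
    results$modules <- list(fit = fit, robustness = rob,
                             anova = anova_tab)
    .stamp_tsv(dplyr::left_join(rob$assignment,
                                dplyr::select(rob$support, "gene",
                                              "support"),
                                by = "gene"),
               file.path(out_dir, "module_assignment.tsv"), run_id)
    if (nrow(fit$eigengenes) > 0) {
      .stamp_tsv(tibble::as_tibble(fit$eigengenes, rownames = "module"),
                 file.path(out_dir, "eigengenes.tsv"), run_id)
    }
    .stamp_tsv(anova_tab, file.path(out_dir, "eigengene_anova.tsv"),
               run_id)
  })

  stage("genesets", {
    gs <- config$genesets
    collection <- if (!is.null(gs$gmt)) {
      read_gmt(gs$gmt)
    } else {
      make_synthetic_collection(rownames(results$preprocess$counts),
                                n_sets = gs$n_synthetic_sets,
                                seed = stage_seed("genesets"))
    }
    ref <- results$de$ref_diet
    runs <- results$de$fold_changes |>
      dplyr::filter(.data$reference == ref) |>
      dplyr::group_by(.data$tissue, .data$pair) |>
      dplyr::group_map(function(d, key) {
        res <- suppressMessages(suppressWarnings(
          run_set_analysis(d, collection, mode = gs$mode,
                           min_size = gs$min_size)))
        if (nrow(res) > 0) {
          dplyr::mutate(res, tissue = key$tissue, pair = key$pair,
                        .before = 1)
        } else NULL
      })
    tab <- dplyr::bind_rows(purrr::compact(runs))
    results$genesets <- tab
    .stamp_tsv(tab, file.path(out_dir, "geneset_results.tsv"), run_id)
  })

  manifest$status <- "complete"
  manifest$seeds <- seeds
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  outputs <- list.files(out_dir, pattern = "\\.tsv$", recursive = TRUE,
                        full.names = TRUE)
  manifest$outputs <- lapply(stats::setNames(outputs,
                                             basename(outputs)),
                             function(f) unname(tools::md5sum(f)))
  write_manifest()
  results$manifest <- manifest
  invisible(results)
}
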