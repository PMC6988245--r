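#' Broom-style tidiers for fitted objects
#'
#' `tidy()` returns the per-unit result table of a fit; `glance()` a
#' one-row summary.
#'
#' @param x a fitted object (`de_fit`, `concordance_test`,
#'   `coexpr_modules`, `module_robustness`).
#' @param ... ignored.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy de_fit
#' @export
tidy.de_fit <- function(x, ...) x$results

#' @rdname tidiers
#' @method glance de_fit
#' @export
glance.de_fit <- function(x, ...) {
  sig <- x$results |>
    dplyr::filter(!is.na(.data$p_adj), .data$p_adj < x$alpha) |>
    dplyr::count(.data$contrast)
  out <- tibble::tibble(
    n_genes = length(unique(x$results$gene)),
    alpha = x$alpha,
    n_unconverged = x$n_unconverged
  )
  for (ct in unique(x$results$contrast)) {
    out[[paste0("n_sig_", ct)]] <- sum(sig$n[sig$contrast == ct])
  }
  out
}

#' @rdname tidiers
#' @method tidy concordance_test
#' @export
tidy.concordance_test <- function(x, ...) x$stats

#' @rdname tidiers
#' @method glance concordance_test
#' @export
glance.concordance_test <- function(x, ...) {
  tibble::tibble(
    tissue = x$stats$tissue[1],
    n_references = nrow(x$stats),
    n_perm = x$stats$n_perm[1],
    min_p_emp = min(x$stats$p_emp_r, x$stats$p_emp_prop)
  )
}

#' @rdname tidiers
#' @method tidy coexpr_modules
#' @export
tidy.coexpr_modules <- function(x, ...) x$assignment

#' @rdname tidiers
#' @method glance coexpr_modules
#' @export
glance.coexpr_modules <- function(x, ...) {
  mods <- setdiff(unique(x$assignment$module), "unassigned")
  tibble::tibble(
    n_modules = length(mods),
    n_assigned = sum(x$assignment$module != "unassigned"),
    n_unassigned = sum(x$assignment$module == "unassigned"),
    mean_var_explained = if (length(mods)) mean(x$var_explained) else
      NA_real_
  )
}

#' @rdname tidiers
#' @method tidy module_robustness
#' @export
tidy.module_robustness <- function(x, ...) x$support

#' @rdname tidiers
#' @method glance module_robustness
#' @export
glance.module_robustness <- function(x, ...) {
  tibble::tibble(
    resamples = x$resamples,
    n_retained = sum(x$assignment$module != "unassigned"),
    n_unassigned = sum(x$assignment$module == "unassigned"),
    median_support = median(x$support$support, na.rm = TRUE)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_genes, "genes,",
      length(x$diets), "diets x", length(x$tissues), "tissues x",
      x$n_replicates, "replicates;",
      length(x$module_spec), "planted module(s); seed", x$seed, "\n")
  invisible(x)
}

#' @export
print.concordance_test <- function(x, ...) {
  cat("Shared-reference concordance test (", x$stats$n_perm[1],
      " permutations)\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' @export
print.soft_threshold <- function(x, ...) {
  cat("Selected soft-thresholding power:", x$power,
      "(target fit", x$target, ")\n")
  invisible(x)
}
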