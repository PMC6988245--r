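#' Proportion of genes trending in the same direction
#'
#' For two log2 fold-change vectors computed against a shared reference,
#' the fraction of genes upregulated in both or downregulated in both:
#' genes with matching nonzero signs over the total number of genes.
#' Genes with either fold change exactly zero count in the denominator
#' only. Invariant to strictly positive rescaling of either vector.
#'
#' @param lfc1,lfc2 equal-length numeric vectors.
#' @return a proportion in \[0, 1\].
#' @export
proportion_same_direction <- function(lfc1, lfc2) {
  if (length(lfc1) != length(lfc2)) stop("length mismatch", call. = FALSE)
  if (length(lfc1) == 0) stop("empty input", call. = FALSE)
  s1 <- sign(lfc1)
  mean(s1 == sign(lfc2) & s1 != 0)
}

#' Pearson correlation of two fold-change vectors
#'
#' @param lfc1,lfc2 numeric vectors of equal length > 2.
#' @return Pearson r, or NA with a warning if either vector is constant.
#' @export
fold_change_correlation <- function(lfc1, lfc2) {
  if (length(lfc1) != length(lfc2)) stop("length mismatch", call. = FALSE)
  if (length(lfc1) < 3) stop("need more than 2 genes", call. = FALSE)
  if (sd(lfc1) == 0 || sd(lfc2) == 0) {
    warning("constant fold-change vector; correlation undefined",
            call. = FALSE)
    return(NA_real_)
  }
  cor(lfc1, lfc2)
}

#' Balanced constrained permutations of diet labels
#'
#' Builds null pseudo-diet assignments that destroy the diet effect while
#' keeping composition balanced: each permutation draws, per true diet,
#' `per_pseudo * n_pseudo` samples without replacement and partitions
#' them so that every pseudo-diet holds exactly `per_pseudo` samples from
#' every true diet. With 6 replicates per diet and 2 per pseudo-diet the
#' labeled partition space has \eqn{(6!/(2!2!2!))^3 = 90^3 = 729{,}000}
#' elements per tissue; draws are uniform with replacement across
#' permutations.
#'
#' @param samples_by_diet named list: diet label -> character vector of
#'   sample ids in that diet.
#' @param n_perm number of permutations.
#' @param per_pseudo samples drawn from each true diet into each
#'   pseudo-diet.
#' @param seed integer seed; same seed gives the identical list.
#' @return list of length `n_perm`; each element a named character vector
#'   mapping sample id -> pseudo-diet label (`"pseudo1"`, ... in the
#'   order of `names(samples_by_diet)`).
#' @export
make_constrained_permutations <- function(samples_by_diet, n_perm = 100,
                                          per_pseudo = 2, seed = 1L) {
  k <- length(samples_by_diet)
  need <- per_pseudo * k
  short <- vapply(samples_by_diet, length, integer(1)) < need
  if (any(short)) {
    stop("insufficient replicates in diet(s): ",
         paste(names(samples_by_diet)[short], collapse = ", "),
         call. = FALSE)
  }
  pseudo <- paste0("pseudo", seq_len(k))
  set.seed(seed)
  lapply(seq_len(n_perm), function(i) {
    assign <- character(0)
    for (s in samples_by_diet) {
      drawn <- sample(s, need)
      assign[drawn] <- rep(pseudo, each = per_pseudo)
    }
    assign
  })
}

#' Empirical p-value from a permutation null
#'
#' The add-one resampling estimate
#' `(1 + #\{null >= observed\}) / (1 + M)` for alternative `"greater"`
#' (`<=` for `"less"`); never returns 0.
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of M null statistics.
#' @param alternative `"greater"` or `"less"`.
#' @return p-value in (0, 1\].
#' @export
empirical_pvalue <- function(observed, null_values,
                             alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(null_values) < 1) stop("empty null", call. = FALSE)
  hits <- if (alternative == "greater") {
    sum(null_values >= observed)
  } else {
    sum(null_values <= observed)
  }
  (1 + hits) / (1 + length(null_values))
}

#' Shared-reference fold-change concordance test
#'
#' For one tissue, quantifies whether the log2 fold changes of two diets,
#' each computed against the same third (reference) diet, trend together:
#' the Pearson correlation of the two fold-change vectors and the
#' proportion of genes changing in the same direction. Because both
#' vectors are ratios against the same reference, even random data yields
#' a positive correlation and a proportion above 1/2 (the
#' shared-reference artifact), so each observed statistic is referred to
#' a constrained-permutation null: `n_perm` pseudo-datasets built by
#' [make_constrained_permutations()], with fold changes recomputed by the
#' identical moderated procedure and one-sided (greater) empirical
#' p-values. Every choice of reference diet is evaluated.
#'
#' The observed statistics do not depend on `seed` (only the null does).
#'
#' @param counts count matrix, genes x samples (all tissues allowed; the
#'   relevant tissue is subset internally).
#' @param meta sample table (`sample_id`, `diet`, `tissue`).
#' @param tissue tissue to analyse; defaults to the single tissue present.
#' @param n_perm number of permutations M.
#' @param per_pseudo samples per true diet in each pseudo-diet.
#' @param seed seed for the permutation draws.
#' @param pseudocount moderation constant for [compute_lfc()].
#' @param genes optional gene subset (e.g. DE-significant genes); default
#'   all genes.
#' @return object of class `concordance_test`: list with `stats` (tibble:
#'   `tissue`, `reference`, `pair`, `n_genes`, `r`, `prop_same`,
#'   `p_emp_r`, `p_emp_prop`, `n_perm`), `nulls` (tibble: `reference`,
#'   `perm`, `r`, `prop_same`), and `lfc` (tibble of the observed fold
#'   changes: `gene`, `reference`, `diet`, `lfc`).
#' @export
run_concordance <- function(counts, meta, tissue = NULL, n_perm = 100,
                            per_pseudo = 2, seed = 1L, pseudocount = 0.5,
                            genes = NULL) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nrow(meta),
            all(colnames(counts) == meta$sample_id))
  tissue <- tissue %||% {
    tt <- unique(meta$tissue)
    if (length(tt) != 1) stop("specify `tissue`", call. = FALSE)
    tt
  }
  keep <- meta$tissue == tissue
  if (!any(keep)) stop("no samples for tissue ", tissue, call. = FALSE)
  meta_t <- meta[keep, , drop = FALSE]
  counts_t <- counts[, meta_t$sample_id, drop = FALSE]
  if (!is.null(genes)) counts_t <- counts_t[genes, , drop = FALSE]
  sf <- estimate_size_factors(counts_t)
  diets <- unique(meta_t$diet)
  if (length(diets) < 3) stop("need at least 3 diets", call. = FALSE)

  samples_by_diet <- split(meta_t$sample_id, factor(meta_t$diet,
                                                    levels = diets))
  perms <- make_constrained_permutations(samples_by_diet, n_perm = n_perm,
                                         per_pseudo = per_pseudo,
                                         seed = seed)

  pair_stats <- function(lfc1, lfc2) {
    c(r = suppressWarnings(fold_change_correlation(lfc1, lfc2)),
      prop = proportion_same_direction(lfc1, lfc2))
  }
  lfc_of <- function(a, b) {
    compute_lfc(counts_t, sf, a, b, pseudocount = pseudocount)$lfc
  }

  stats_rows <- list(); null_rows <- list(); lfc_rows <- list()
  for (i in seq_along(diets)) {
    ref <- diets[i]
    others <- setdiff(diets, ref)[1:2]
    l1 <- lfc_of(samples_by_diet[[others[1]]], samples_by_diet[[ref]])
    l2 <- lfc_of(samples_by_diet[[others[2]]], samples_by_diet[[ref]])
    obs <- pair_stats(l1, l2)
    lfc_rows[[ref]] <- tibble::tibble(
      gene = rep(rownames(counts_t), 2),
      reference = ref,
      diet = rep(others, each = nrow(counts_t)),
      lfc = c(l1, l2)
    )

    null_mat <- vapply(perms, function(p) {
      grp <- split(names(p), p)
      j <- setdiff(seq_along(diets), i)
      n1 <- lfc_of(grp[[paste0("pseudo", j[1])]],
                   grp[[paste0("pseudo", i)]])
      n2 <- lfc_of(grp[[paste0("pseudo", j[2])]],
                   grp[[paste0("pseudo", i)]])
      pair_stats(n1, n2)
    }, numeric(2))
    null_rows[[ref]] <- tibble::tibble(
      reference = ref, perm = seq_len(n_perm),
      r = null_mat["r", ], prop_same = null_mat["prop", ]
    )
    stats_rows[[ref]] <- tibble::tibble(
      tissue = tissue, reference = ref,
      pair = paste(others[1], "&", others[2], "vs", ref),
      n_genes = nrow(counts_t),
      r = unname(obs["r"]), prop_same = unname(obs["prop"]),
      p_emp_r = empirical_pvalue(obs["r"], null_mat["r", ]),
      p_emp_prop = empirical_pvalue(obs["prop"], null_mat["prop", ]),
      n_perm = n_perm
    )
  }

  structure(
    list(stats = dplyr::bind_rows(stats_rows),
         nulls = dplyr::bind_rows(null_rows),
         lfc = dplyr::bind_rows(lfc_rows)),
    class = "concordance_test"
  )
}
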