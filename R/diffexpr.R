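#' Method-of-moments negative-binomial dispersion per gene
#'
#' On size-factor-normalized counts, pools unbiased within-cell variances
#' across the design cells (degrees-of-freedom weighted) and sets
#' \eqn{\hat\alpha_g = \max(\alpha_{floor}, (s^2_g - \bar\mu_g) / \bar\mu_g^2)},
#' the moment estimator under the NB variance \eqn{\mu + \alpha\mu^2}.
#' Poisson-like or constant genes hit the floor; constant genes trigger a
#' warning.
#'
#' @param counts count matrix, genes x samples.
#' @param size_factors from [estimate_size_factors()].
#' @param groups factor of design cells (e.g. diet x tissue interaction),
#'   one entry per sample.
#' @param floor minimum dispersion returned.
#' @return named numeric vector of dispersions.
#' @export
estimate_dispersion <- function(counts, size_factors, groups,
                                floor = 1e-8) {
  counts <- as.matrix(counts)
  groups <- factor(groups)
  stopifnot(ncol(counts) == length(size_factors),
            ncol(counts) == length(groups))
  norm <- sweep(counts, 2, size_factors, `/`)
  mu <- rowMeans(norm)
  lv <- lapply(levels(groups), function(g) {
    sub <- norm[, groups == g, drop = FALSE]
    n <- ncol(sub)
    list(ss = if (n > 1) rowSums((sub - rowMeans(sub))^2) else
           rep(0, nrow(sub)),
         df = max(n - 1, 0))
  })
  ss <- Reduce(`+`, lapply(lv, `[[`, "ss"))
  df <- sum(vapply(lv, `[[`, numeric(1), "df"))
  if (df == 0) stop("no residual degrees of freedom within cells",
                    call. = FALSE)
  s2 <- ss / df
  if (any(s2 == 0)) {
    warning(sum(s2 == 0), " constant gene(s): dispersion set to floor",
            call. = FALSE)
  }
  alpha <- ifelse(mu > 0, pmax(floor, (s2 - mu) / mu^2), floor)
  names(alpha) <- rownames(counts)
  alpha
}

#' Fit a negative-binomial GLM for one gene
#'
#' Maximizes the NB log-likelihood with log link, log size-factor
#' offsets and fixed dispersion `alpha` (IRLS; gradient tolerance 1e-8,
#' at most 100 iterations). Coefficients are reported on the log2 scale.
#'
#' @param y integer counts for one gene, length = samples.
#' @param size_factors positive sample depth factors.
#' @param X full-rank design matrix (samples x coefficients).
#' @param alpha NB dispersion for this gene.
#' @return list of class `gene_fit`: `coef` (log2), `fitted`,
#'   `dispersion`, `loglik`, `converged`.
#' @export
fit_nb_glm <- function(y, size_factors, X, alpha) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(size_factors) == length(y),
            alpha > 0)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design", call. = FALSE)
  if (all(y == 0)) stop("all-zero gene", call. = FALSE)
  fam <- MASS::negative.binomial(theta = 1 / alpha)
  fit <- suppressWarnings(glm.fit(
    X, y, family = fam, offset = log(size_factors),
    control = glm.control(epsilon = 1e-8, maxit = 100)
  ))
  mu <- fit$fitted.values
  structure(
    list(coef = fit$coefficients / log(2),
         fitted = mu,
         dispersion = alpha,
         loglik = sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE)),
         converged = isTRUE(fit$converged)),
    class = "gene_fit"
  )
}

#' Likelihood-ratio test between nested gene fits
#'
#' `stat = max(0, 2 (ll_full - ll_reduced))` referred to the chi-square
#' upper tail with `df` degrees of freedom (difference in coefficient
#' count when `df` is omitted).
#'
#' @param full,reduced `gene_fit` objects for nested models.
#' @param df degrees of freedom; defaults to the coefficient-count
#'   difference.
#' @return list with `stat`, `df`, `p`.
#' @export
lrt_nested <- function(full, reduced, df = NULL) {
  stopifnot(inherits(full, "gene_fit"), inherits(reduced, "gene_fit"))
  if (is.null(df)) df <- length(full$coef) - length(reduced$coef)
  if (df < 1) stop("models are not nested (full must have more terms)",
                   call. = FALSE)
  nf <- names(full$coef); nr <- names(reduced$coef)
  if (!is.null(nf) && !is.null(nr) && !all(nr %in% nf)) {
    stop("models are not nested: reduced terms are not a subset",
         call. = FALSE)
  }
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values, capped at 1, monotone in rank. Missing
#' values are excluded from the family and propagated.
#'
#' @param pvals numeric vector in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Moderated log2 fold change between two sample groups
#'
#' `log2((mean_A + c) / (mean_B + c))` on size-factor-normalized counts,
#' with a pseudocount `c` damping low-expression ratios (a deterministic,
#' closed-form moderation of the fold change). Also reports the base mean
#' over both groups. Antisymmetric: LFC(A vs B) = -LFC(B vs A).
#'
#' @param counts count matrix, genes x samples.
#' @param size_factors from [estimate_size_factors()].
#' @param samples_a,samples_b disjoint non-empty character vectors of
#'   sample ids (columns of `counts`); `samples_a` is the numerator.
#' @param pseudocount moderation constant `c`.
#' @return tibble with `gene`, `lfc`, `base_mean`.
#' @export
compute_lfc <- function(counts, size_factors, samples_a, samples_b,
                        pseudocount = 0.5) {
  counts <- as.matrix(counts)
  stopifnot(length(samples_a) > 0, length(samples_b) > 0,
            !any(samples_a %in% samples_b))
  miss <- setdiff(c(samples_a, samples_b), colnames(counts))
  if (length(miss) > 0) {
    stop("unknown samples: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  norm <- sweep(counts, 2, size_factors[colnames(counts)], `/`)
  mu_a <- rowMeans(norm[, samples_a, drop = FALSE])
  mu_b <- rowMeans(norm[, samples_b, drop = FALSE])
  tibble::tibble(
    gene = rownames(counts),
    lfc = unname(log2((mu_a + pseudocount) / (mu_b + pseudocount))),
    base_mean = unname(rowMeans(norm[, c(samples_a, samples_b),
                                     drop = FALSE]))
  )
}

# Model formulas of the nested-model scheme. Base terms are SV (if
# available) and batch; contrasts are tissue main effect (m3 vs m2),
# treatment main effect (m3 vs m1), and the interaction (m4 vs m3).
.de_designs <- function(meta, sv, ref_diet, ref_tissue) {
  dat <- data.frame(
    diet = stats::relevel(factor(meta$diet), ref = ref_diet),
    batch = factor(meta$batch)
  )
  multi_tissue <- length(unique(meta$tissue)) > 1
  if (multi_tissue) {
    dat$tissue <- stats::relevel(factor(meta$tissue), ref = ref_tissue)
  }
  base <- "~ batch"
  if (!is.null(sv)) {
    dat$sv <- sv
    base <- "~ sv + batch"
  }
  f <- function(extra) {
    model.matrix(stats::as.formula(paste(base, extra)), dat)
  }
  if (multi_tissue) {
    list(
      m1 = f("+ tissue"),
      m2 = f("+ diet"),
      m3 = f("+ tissue + diet"),
      m4 = f("+ tissue + diet + tissue:diet"),
      contrasts = list(
        tissue = c("m3", "m2"),
        treatment = c("m3", "m1"),
        interaction = c("m4", "m3")
      )
    )
  } else {
    list(
      m0 = f(""),
      m2 = f("+ diet"),
      contrasts = list(treatment = c("m2", "m0"))
    )
  }
}

#' Nested-model differential expression over diets and tissues
#'
#' Fits per-gene negative-binomial GLMs (log link, size-factor offsets,
#' gene-wise moment dispersions) for the nested model scheme
#' `expression ~ SV + batch (+ tissue) (+ treatment) (+ tissue:treatment)`
#' and performs likelihood-ratio tests for the tissue main effect,
#' treatment (diet) main effect, and tissue-by-treatment interaction,
#' with Benjamini-Hochberg adjustment per contrast. With a single tissue
#' in `meta` only the treatment contrast is tested. Also computes, per
#' tissue, moderated log2 fold changes for every ordered pair of diets
#' (each non-reference diet against each possible reference diet).
#'
#' Genes whose fits do not converge get missing p-values and are excluded
#' from the adjustment; their count is reported in `glance()`.
#'
#' @param counts filtered count matrix, genes x samples.
#' @param meta sample table (`sample_id`, `diet`, `tissue`, `batch`).
#' @param sv optional surrogate-variable vector (one value per sample) or
#'   a `design_info` object.
#' @param alpha FDR threshold used when summarizing significant genes.
#' @param pseudocount moderation constant for [compute_lfc()].
#' @param dispersion_floor floor for [estimate_dispersion()].
#' @param ref_diet,ref_tissue reference factor levels (default `"C"` and
#'   `"B"` when present).
#' @return object of class `de_fit`: list with `results` (tibble: `gene`,
#'   `contrast`, `stat`, `df`, `p`, `p_adj`), `fold_changes` (tibble:
#'   `gene`, `tissue`, `diet`, `reference`, `pair`, `lfc`, `base_mean`),
#'   `size_factors`, `dispersions`, `alpha`, `n_unconverged`.
#' @export
run_de <- function(counts, meta, sv = NULL, alpha = 0.05,
                   pseudocount = 0.5, dispersion_floor = 1e-8,
                   ref_diet = NULL, ref_tissue = NULL) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nrow(meta),
            all(colnames(counts) == meta$sample_id))
  if (inherits(sv, "design_info")) sv <- sv$sv
  diets <- unique(meta$diet)
  tissues <- unique(meta$tissue)
  ref_diet <- ref_diet %||% (if ("C" %in% diets) "C" else diets[1])
  ref_tissue <- ref_tissue %||% (if ("B" %in% tissues) "B" else tissues[1])

  sf <- estimate_size_factors(counts)
  cells <- interaction(meta$diet, meta$tissue, drop = TRUE)
  disp <- estimate_dispersion(counts, sf, cells, floor = dispersion_floor)

  dg <- .de_designs(meta, sv, ref_diet, ref_tissue)
  model_names <- setdiff(names(dg), "contrasts")
  genes <- rownames(counts)

  fits <- lapply(model_names, function(m) {
    X <- dg[[m]]
    lapply(seq_along(genes), function(i) {
      tryCatch(fit_nb_glm(counts[i, ], sf, X, disp[i]),
               error = function(e) NULL)
    })
  })
  names(fits) <- model_names

  usable <- function(f) !is.null(f) && f$converged
  results <- purrr::imap(dg$contrasts, function(models, cname) {
    fullf <- fits[[models[1]]]
    redf <- fits[[models[2]]]
    df <- ncol(dg[[models[1]]]) - ncol(dg[[models[2]]])
    rows <- purrr::map(seq_along(genes), function(i) {
      if (usable(fullf[[i]]) && usable(redf[[i]])) {
        lr <- lrt_nested(fullf[[i]], redf[[i]], df = df)
        tibble::tibble(gene = genes[i], contrast = cname,
                       stat = lr$stat, df = lr$df, p = lr$p)
      } else {
        tibble::tibble(gene = genes[i], contrast = cname,
                       stat = NA_real_, df = df, p = NA_real_)
      }
    })
    dplyr::bind_rows(rows) |>
      dplyr::mutate(p_adj = bh_adjust(.data$p))
  }) |>
    dplyr::bind_rows()

  n_unconv <- sum(is.na(results$p)) / length(dg$contrasts)

  fold_changes <- purrr::map(tissues, function(t) {
    idx <- meta$tissue == t
    purrr::map(diets, function(ref) {
      purrr::map(setdiff(diets, ref), function(d) {
        compute_lfc(counts[, idx, drop = FALSE], sf[idx],
                    meta$sample_id[idx & meta$diet == d],
                    meta$sample_id[idx & meta$diet == ref],
                    pseudocount = pseudocount) |>
          dplyr::mutate(tissue = t, diet = d, reference = ref,
                        pair = paste(d, "vs", ref), .before = 1)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("gene", "tissue", "diet", "reference", "pair",
                  "lfc", "base_mean")

  structure(
    list(results = results, fold_changes = fold_changes,
         size_factors = sf, dispersions = disp, alpha = alpha,
         n_unconverged = n_unconv,
         ref_diet = ref_diet, ref_tissue = ref_tissue),
    class = "de_fit"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
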