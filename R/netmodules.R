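#' Signed weighted adjacency matrix
#'
#' \eqn{a_{ij} = ((1 + cor_{ij}) / 2)^\beta} with Pearson correlation
#' across samples, so anti-correlated genes get near-zero connection
#' strength. Diagonal is 1. Constant genes (undefined correlation) are
#' treated as uncorrelated (correlation 0) with a message.
#'
#' @param expr expression matrix (log2 scale), genes x samples, >= 3
#'   samples.
#' @param power soft-thresholding exponent \eqn{\beta \ge 1}.
#' @return symmetric genes x genes matrix with entries in \[0, 1\].
#' @export
signed_adjacency <- function(expr, power = 23) {
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) >= 3, power >= 1)
  C <- suppressWarnings(cor(t(expr)))
  if (anyNA(C)) {
    n_const <- sum(.row_vars(expr) == 0)
    message(n_const, " constant gene(s): correlations treated as 0")
    C[is.na(C)] <- 0
  }
  A <- ((1 + C) / 2)^power
  diag(A) <- 1
  A
}

#' Scale-free topology fit index of a connectivity vector
#'
#' Bins connectivities into `n_bins` equal-occupancy bins and regresses
#' the log10 frequency density of each bin (occupancy fraction divided
#' by bin width, so equal-occupancy binning still resolves the shape of
#' the degree distribution) on the log10 mean connectivity, returning
#' \eqn{R^2 \times sign(-slope)}: positive when the degree distribution
#' decays like a power law.
#'
#' @param k non-negative connectivities.
#' @param n_bins number of equal-occupancy bins.
#' @return the signed fit index, or NA with a warning when degenerate.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) {
    warning("degenerate connectivity distribution", call. = FALSE)
    return(NA_real_)
  }
  breaks <- unique(quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  dens <- (tapply(k, bin, length) / length(k)) / diff(breaks)
  ok <- !is.na(mean_k) & dens > 0
  if (sum(ok) < 3) {
    warning("too few occupied bins for a scale-free fit", call. = FALSE)
    return(NA_real_)
  }
  fit <- lm.fit(cbind(1, log10(mean_k[ok])), log10(dens[ok]))
  r2 <- 1 - sum(fit$residuals^2) /
    sum((log10(dens[ok]) - mean(log10(dens[ok])))^2)
  r2 * sign(-fit$coefficients[2])
}

#' Choose a soft-thresholding power by scale-free fit
#'
#' Computes, for each candidate power, the whole-network connectivities
#' \eqn{k_i = \sum_{j \ne i} a_{ij}} of the signed adjacency and their
#' scale-free fit index, and returns the smallest power whose fit reaches
#' `target`; if none does, the power with the maximal fit is returned
#' with a warning.
#'
#' @param expr expression matrix, genes x samples.
#' @param powers candidate powers (>= 2 values unless fixing one).
#' @param target fit index to reach (conventionally 0.90).
#' @param n_bins bins for [scale_free_fit()].
#' @return list of class `soft_threshold`: `power`, `fits` (tibble:
#'   `power`, `fit`, `mean_k`), `target`.
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, seq(12, 30, 2)),
                                target = 0.90, n_bins = 10) {
  expr <- as.matrix(expr)
  stopifnot(length(powers) >= 1)
  C <- suppressWarnings(cor(t(expr)))
  C[is.na(C)] <- 0
  base <- (1 + C) / 2
  diag(base) <- 0  # exclude self-connectivity
  fits <- purrr::map_dfr(powers, function(b) {
    k <- rowSums(base^b)
    tibble::tibble(power = b,
                   fit = suppressWarnings(scale_free_fit(k, n_bins)),
                   mean_k = mean(k))
  })
  reached <- fits$power[!is.na(fits$fit) & fits$fit >= target]
  if (length(reached) > 0) {
    power <- min(reached)
  } else {
    warning("no candidate power reaches the target fit of ", target,
            "; returning the best fit", call. = FALSE)
    power <- fits$power[which.max(fits$fit)]
  }
  structure(list(power = power, fits = fits, target = target),
            class = "soft_threshold")
}

#' Topological overlap matrix
#'
#' Augments direct adjacency with shared-neighbour agreement:
#' \deqn{TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' for \eqn{i \ne j}, with connectivity \eqn{k} excluding the diagonal,
#' and \eqn{TOM_{ii} = 1}.
#'
#' @param adjacency symmetric matrix in \[0, 1\] with unit diagonal.
#' @return symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  A <- as.matrix(adjacency)
  if (!isSymmetric(unname(A), tol = 1e-10)) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  k <- rowSums(A) - 1
  # (A^2)_ij counts a_ii*a_ij + a_ij*a_jj = 2 a_ij extra terms; the TOM
  # numerator is therefore (A^2)_ij - a_ij.
  num <- A %*% A - A
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  pmin(pmax(tom, 0), 1)
}

#' Average-linkage clustering of the TOM and static height cut
#'
#' Hierarchical clustering (average linkage) on the dissimilarity
#' `1 - TOM`, cut at a fixed height; clusters smaller than `min_size`
#' are sent to the distinguished `"unassigned"` module (the grey-module
#' convention). Retained modules are labelled `M1`, `M2`, ... in order
#' of decreasing size.
#'
#' @param tom topological overlap matrix from [topological_overlap()].
#' @param cut_height static cut height on `1 - TOM`.
#' @param min_size minimum module size.
#' @return list: `dendrogram` (an `hclust`), `assignment` (tibble:
#'   `gene`, `module`).
#' @export
cluster_and_cut <- function(tom, cut_height = 0.95, min_size = 30) {
  tom <- as.matrix(tom)
  genes <- rownames(tom) %||% paste0("g", seq_len(nrow(tom)))
  h <- hclust(as.dist(1 - tom), method = "average")
  cl <- cutree(h, h = cut_height)
  sizes <- sort(table(cl), decreasing = TRUE)
  big <- names(sizes)[sizes >= min_size]
  label <- rep("unassigned", length(cl))
  for (i in seq_along(big)) {
    label[cl == as.integer(big[i])] <- paste0("M", i)
  }
  list(dendrogram = h,
       assignment = tibble::tibble(gene = genes, module = label))
}

#' Module eigengene (first principal component)
#'
#' The first principal component across samples of the gene-standardized
#' (zero mean, unit variance per gene) member submatrix: a one-row
#' summary profile of the module, with unit norm across samples. The
#' sign is oriented so the eigengene correlates non-negatively with the
#' module's mean standardized profile (ties broken by making the
#' largest-magnitude element positive).
#'
#' @param expr expression matrix, genes x samples (>= 3 samples).
#' @param genes member gene ids (>= 2).
#' @return list: `eigengene` (named numeric, unit norm),
#'   `var_explained` (fraction in \[0, 1\]).
#' @export
module_eigengene <- function(expr, genes) {
  expr <- as.matrix(expr)
  stopifnot(length(genes) >= 2, ncol(expr) >= 3)
  sub <- expr[genes, , drop = FALSE]
  v <- .row_vars(sub)
  if (all(v == 0)) stop("all member genes are constant", call. = FALSE)
  S <- (sub - rowMeans(sub)) / sqrt(v)
  S[v == 0, ] <- 0
  dec <- svd(S, nu = 0, nv = 1)
  e <- dec$v[, 1]
  m <- colMeans(S)
  orient <- sum(e * m)
  if (orient < 0 || (orient == 0 && e[which.max(abs(e))] < 0)) e <- -e
  names(e) <- colnames(expr)
  list(eigengene = e, var_explained = dec$d[1]^2 / sum(dec$d^2))
}

#' Eigengenes for every module in an assignment
#'
#' @param expr expression matrix, genes x samples.
#' @param assignment tibble (`gene`, `module`); `"unassigned"` is
#'   skipped.
#' @return list: `eigengenes` (module x sample matrix, unit-norm rows),
#'   `var_explained` (named vector).
#' @export
module_eigengenes <- function(expr, assignment) {
  mods <- sort(setdiff(unique(assignment$module), "unassigned"))
  if (length(mods) == 0) {
    return(list(eigengenes = matrix(0, 0, ncol(expr),
                                    dimnames = list(NULL, colnames(expr))),
                var_explained = numeric(0)))
  }
  es <- lapply(mods, function(m) {
    module_eigengene(expr, assignment$gene[assignment$module == m])
  })
  list(
    eigengenes = do.call(rbind, c(lapply(es, `[[`, "eigengene"),
                                  list(deparse.level = 0))) |>
      `rownames<-`(mods),
    var_explained = stats::setNames(
      vapply(es, `[[`, numeric(1), "var_explained"), mods)
  )
}

#' Merge modules with highly correlated eigengenes
#'
#' Iteratively merges the module pair with the highest eigengene
#' correlation strictly above `threshold`, recomputing eigengenes after
#' each merge, until no pair exceeds the threshold. The merged module
#' keeps the lexicographically smaller label; `"unassigned"` never
#' merges.
#'
#' @param expr expression matrix, genes x samples.
#' @param assignment tibble (`gene`, `module`).
#' @param threshold eigengene correlation above which modules merge.
#' @return the merged assignment tibble.
#' @export
merge_similar_modules <- function(expr, assignment, threshold = 0.9) {
  assignment <- assignment
  repeat {
    me <- module_eigengenes(expr, assignment)
    if (nrow(me$eigengenes) < 2) break
    C <- cor(t(me$eigengenes))
    diag(C) <- -Inf
    best <- which(C == max(C), arr.ind = TRUE)[1, ]
    if (C[best[1], best[2]] <= threshold) break
    labs <- sort(rownames(C)[best])
    assignment$module[assignment$module == labs[2]] <- labs[1]
  }
  assignment
}

#' Detect co-expression modules in one pass
#'
#' Signed adjacency at `power`, topological overlap, average-linkage
#' clustering with a static height cut and minimum module size, then
#' eigengene-based merging. Defaults are power 23, cut
#' height 0.95, minimum size 30, merge threshold 0.9.
#'
#' @param expr expression matrix (log2, batch-corrected), genes x
#'   samples.
#' @param power soft-thresholding power.
#' @param cut_height static cut height on `1 - TOM`.
#' @param min_size minimum module size.
#' @param merge_threshold eigengene correlation for merging.
#' @return object of class `coexpr_modules`: `assignment` (tibble),
#'   `eigengenes` (module x sample matrix), `var_explained`,
#'   `dendrogram`, `params`.
#' @export
detect_modules <- function(expr, power = 23, cut_height = 0.95,
                           min_size = 30, merge_threshold = 0.9) {
  expr <- as.matrix(expr)
  A <- signed_adjacency(expr, power = power)
  tom <- topological_overlap(A)
  cc <- cluster_and_cut(tom, cut_height = cut_height, min_size = min_size)
  assignment <- merge_similar_modules(expr, cc$assignment,
                                      threshold = merge_threshold)
  me <- module_eigengenes(expr, assignment)
  structure(
    list(assignment = assignment, eigengenes = me$eigengenes,
         var_explained = me$var_explained, dendrogram = cc$dendrogram,
         params = list(power = power, cut_height = cut_height,
                       min_size = min_size,
                       merge_threshold = merge_threshold)),
    class = "coexpr_modules"
  )
}

#' Module-membership robustness by replicate resampling
#'
#' Rebuilds the network `resamples` times on datasets keeping `kept`
#' replicates per diet-by-tissue cell (drawn without replacement), with
#' the identical network parameters including merging. Each resampled
#' module is matched to the full-data module with which it shares at
#' least `match_fraction` of that full-data module's genes (largest
#' absolute overlap wins; ties go to the lexicographically smallest
#' full-data label). A gene's support is the fraction of resamples in
#' which it lands in a module matched to its full-data module; genes
#' with support below `support_threshold` are unassigned in the final
#' assignment.
#'
#' @param expr expression matrix, genes x samples.
#' @param meta sample table (`sample_id`, `diet`, `tissue`,
#'   `replicate`).
#' @param full a `coexpr_modules` fit on the full data (its `params` are
#'   reused).
#' @param resamples number of resampled networks.
#' @param kept replicates kept per diet-by-tissue cell.
#' @param match_fraction minimum shared fraction of a full-data module's
#'   genes for a resampled module to match it.
#' @param support_threshold minimum support to stay assigned.
#' @param seed integer seed.
#' @return object of class `module_robustness`: `support` (tibble:
#'   `gene`, `module`, `support`), `module_matches` (tibble: `module`,
#'   `times_matched`), `assignment` (tibble, final robust assignment),
#'   `resamples`.
#' @export
resample_robustness <- function(expr, meta, full, resamples = 100,
                                kept = 4, match_fraction = 0.10,
                                support_threshold = 0.50, seed = 1L) {
  stopifnot(inherits(full, "coexpr_modules"))
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == nrow(meta),
            all(colnames(expr) == meta$sample_id))
  cells <- split(meta$sample_id, interaction(meta$diet, meta$tissue,
                                             drop = TRUE))
  if (any(vapply(cells, length, integer(1)) < kept)) {
    stop("`kept` exceeds available replicates in at least one cell",
         call. = FALSE)
  }
  full_mods <- sort(setdiff(unique(full$assignment$module), "unassigned"))
  full_sets <- lapply(full_mods, function(m) {
    full$assignment$gene[full$assignment$module == m]
  })
  names(full_sets) <- full_mods
  gene_mod <- stats::setNames(full$assignment$module, full$assignment$gene)

  hits <- stats::setNames(numeric(nrow(full$assignment)),
                          full$assignment$gene)
  times_matched <- stats::setNames(numeric(length(full_mods)), full_mods)

  set.seed(seed)
  p <- full$params
  for (r in seq_len(resamples)) {
    keep <- unlist(lapply(cells, function(s) sample(s, kept)),
                   use.names = FALSE)
    keep <- meta$sample_id[meta$sample_id %in% keep]  # original order
    fit_r <- detect_modules(expr[, keep, drop = FALSE], power = p$power,
                            cut_height = p$cut_height,
                            min_size = p$min_size,
                            merge_threshold = p$merge_threshold)
    r_mods <- setdiff(unique(fit_r$assignment$module), "unassigned")
    for (rm in r_mods) {
      rgenes <- fit_r$assignment$gene[fit_r$assignment$module == rm]
      ov <- vapply(full_sets, function(fs) length(intersect(rgenes, fs)),
                   numeric(1))
      eligible <- ov >= match_fraction *
        vapply(full_sets, length, numeric(1))
      if (!any(eligible)) next
      cand <- names(full_sets)[eligible]
      matched <- cand[order(-ov[eligible], cand)][1]
      times_matched[matched] <- times_matched[matched] + 1
      supported <- rgenes[gene_mod[rgenes] == matched]
      supported <- supported[!is.na(gene_mod[supported])]
      hits[supported] <- hits[supported] + 1
    }
  }

  support <- tibble::tibble(
    gene = full$assignment$gene,
    module = full$assignment$module,
    support = ifelse(full$assignment$module == "unassigned", NA_real_,
                     hits[full$assignment$gene] / resamples)
  )
  final <- support |>
    dplyr::mutate(module = ifelse(
      !is.na(.data$support) & .data$support >= support_threshold,
      .data$module, "unassigned")) |>
    dplyr::select("gene", "module")

  structure(
    list(support = support,
         module_matches = tibble::tibble(
           module = full_mods,
           times_matched = as.numeric(times_matched)),
         assignment = final, resamples = resamples),
    class = "module_robustness"
  )
}

#' Two-way ANOVA on module eigengenes
#'
#' For each module eigengene, fits `eigengene ~ diet * tissue` (or
#' `~ diet` with a single tissue) on a balanced design and reports the
#' F statistic and p-value for each term, with Benjamini-Hochberg
#' adjustment across modules within each term. Under balance the
#' sequential sums of squares equal the marginal ones. Errors on an
#' unbalanced design.
#'
#' @param eigengenes module x sample matrix (or a `coexpr_modules`
#'   object).
#' @param meta sample table with `diet` and `tissue`, rows matching the
#'   eigengene columns.
#' @return tibble: `module`, `term`, `df`, `statistic`, `p`, `p_adj`.
#' @export
eigengene_anova <- function(eigengenes, meta) {
  if (inherits(eigengenes, "coexpr_modules")) {
    eigengenes <- eigengenes$eigengenes
  }
  eigengenes <- as.matrix(eigengenes)
  empty <- tibble::tibble(module = character(0), term = character(0),
                          df = numeric(0), statistic = numeric(0),
                          p = numeric(0), p_adj = numeric(0))
  if (nrow(eigengenes) == 0) return(empty)
  stopifnot(ncol(eigengenes) == nrow(meta))
  multi_tissue <- length(unique(meta$tissue)) > 1
  tab <- if (multi_tissue) table(meta$diet, meta$tissue) else
    table(meta$diet)
  if (length(unique(as.vector(tab))) != 1) {
    stop("design must be balanced (equal replicates in every ",
         "diet-by-tissue cell) for the eigengene ANOVA", call. = FALSE)
  }
  form <- if (multi_tissue) e ~ diet * tissue else e ~ diet
  rows <- purrr::map(rownames(eigengenes), function(m) {
    dat <- data.frame(e = eigengenes[m, ],
                      diet = factor(meta$diet),
                      tissue = factor(meta$tissue))
    sm <- summary(aov(form, data = dat))[[1]]
    terms <- trimws(rownames(sm))
    keep <- terms != "Residuals"
    tibble::tibble(module = m, term = terms[keep], df = sm$Df[keep],
                   statistic = sm$`F value`[keep],
                   p = sm$`Pr(>F)`[keep])
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$term) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p)) |>
    dplyr::ungroup()
}
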