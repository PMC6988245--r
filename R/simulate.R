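#' Configuration for the diet-by-tissue count simulator
#'
#' Builds and validates the parameter set for [simulate_counts()]. The
#' defaults emulate a three-diet (control `C`, dietary restriction `DR`,
#' high sugar `HS`) by three-tissue (body `B`, head `H`, ovary `O`)
#' factorial with six replicate batches per cell, i.e. 54 samples, 18 per
#' diet. Counts are negative binomial around a log-normal baseline with
#' tissue-dominant structure, subtle diet effects, per-batch offsets,
#' planted concordant diet responses, and optional correlated gene modules
#' driven by latent factors.
#'
#' All planted effects live on the log2 scale: the expected count for gene
#' \eqn{g} in sample \eqn{j} is
#' \deqn{\mu_{gj} = depth_j \cdot 2^{b_g + t_{g,tissue(j)} + \delta_{g,diet(j),tissue(j)} + \beta_{batch(j)} + \ell_g f_{m(g),j}}}
#' with NB dispersion `dispersion` (variance \eqn{\mu + \alpha \mu^2}).
#'
#' @param n_genes number of genes to simulate.
#' @param diets diet labels; the first is the reference (no planted effect).
#' @param tissues tissue labels.
#' @param n_replicates replicates per diet-by-tissue cell; replicate index
#'   doubles as the batch label, each batch containing every cell once.
#' @param baseline_logmean_mu,baseline_logmean_sigma mean and sd of the
#'   per-gene baseline log2 abundance.
#' @param dispersion NB dispersion \eqn{\alpha} (variance
#'   \eqn{\mu + \alpha\mu^2}).
#' @param pi_de fraction of genes with a planted diet effect.
#' @param effect_size_sd sd of planted log2 diet-effect magnitudes
#'   (magnitudes are `|N(0, effect_size_sd)|`).
#' @param fixed_effect_size optional; when set, every planted effect has
#'   exactly this magnitude (signs still follow `rho_concord`).
#' @param rho_concord among diet-affected genes, the exact fraction whose
#'   effects for the second and third diet (relative to the reference)
#'   share a sign. Constructed, not sampled.
#' @param tissue_effect_sd sd of per-gene, per-tissue log2 offsets
#'   (tissue-dominant expression structure).
#' @param interaction_sd sd of the log-normal tissue-specific multiplier
#'   applied to each planted diet effect; produces diet-by-tissue
#'   interaction while preserving the sign of the effect in every tissue.
#' @param batch_effect_sd sd of the scalar per-batch log2 offset shared by
#'   all genes.
#' @param module_spec list of planted co-expression modules, each a
#'   two-element vector `c(size, loading_sd)`; gene loadings on the module
#'   latent factor are `|N(0, loading_sd)|` so within-module correlations
#'   are positive (detectable by a signed network).
#' @param library_size_range sequencing-depth multipliers are drawn
#'   log-uniform on this interval (default matches a reported size-factor
#'   spread of roughly 0.5--2).
#' @param seed integer seed; identical config + seed gives bitwise
#'   identical output.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_counts()]
#' @export
sim_config <- function(n_genes = 2000,
                       diets = c("C", "DR", "HS"),
                       tissues = c("B", "H", "O"),
                       n_replicates = 6,
                       baseline_logmean_mu = 5,
                       baseline_logmean_sigma = 2,
                       dispersion = 0.05,
                       pi_de = 0.2,
                       effect_size_sd = 0.5,
                       fixed_effect_size = NULL,
                       rho_concord = 0.75,
                       tissue_effect_sd = 2,
                       interaction_sd = 0.25,
                       batch_effect_sd = 0.2,
                       module_spec = list(),
                       library_size_range = c(0.5, 2),
                       seed = 1L) {
  stopifnot(
    length(n_genes) == 1, n_genes >= 1,
    length(diets) >= 1, !anyDuplicated(diets),
    length(tissues) >= 1, !anyDuplicated(tissues),
    n_replicates >= 1
  )
  if (dispersion <= 0) stop("`dispersion` must be positive", call. = FALSE)
  for (p in c(pi_de = pi_de, rho_concord = rho_concord)) {
    if (p < 0 || p > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(library_size_range <= 0) || length(library_size_range) != 2 ||
      library_size_range[1] > library_size_range[2]) {
    stop("`library_size_range` must be an increasing pair of positive reals",
         call. = FALSE)
  }
  module_spec <- lapply(module_spec, function(m) {
    m <- as.numeric(m)
    if (length(m) != 2 || m[1] < 2 || m[2] < 0) {
      stop("each module_spec entry must be c(size >= 2, loading_sd >= 0)",
           call. = FALSE)
    }
    m
  })
  if (length(module_spec) > 0 &&
      sum(vapply(module_spec, `[`, numeric(1), 1)) > n_genes) {
    stop("module sizes exceed `n_genes`", call. = FALSE)
  }
  structure(
    list(
      n_genes = as.integer(n_genes), diets = diets, tissues = tissues,
      n_replicates = as.integer(n_replicates),
      baseline_logmean_mu = baseline_logmean_mu,
      baseline_logmean_sigma = baseline_logmean_sigma,
      dispersion = dispersion, pi_de = pi_de,
      effect_size_sd = effect_size_sd,
      fixed_effect_size = fixed_effect_size,
      rho_concord = rho_concord,
      tissue_effect_sd = tissue_effect_sd,
      interaction_sd = interaction_sd,
      batch_effect_sd = batch_effect_sd,
      module_spec = module_spec,
      library_size_range = library_size_range,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a diet-by-tissue RNA-seq count experiment with ground truth
#'
#' Draws a gene-by-sample integer count matrix from the generative model
#' described in [sim_config()], together with the sample design table and
#' the planted truth (per-gene, per-diet, per-tissue log2 fold changes,
#' DE and concordance flags, module labels, batch offsets, sample depths).
#'
#' @param config a [sim_config()] object.
#'
#' @return A list of class `diet_sim`:
#' \describe{
#'   \item{counts}{integer matrix, genes x samples.}
#'   \item{meta}{tibble with `sample_id`, `diet`, `tissue`, `replicate`,
#'     `batch`.}
#'   \item{truth}{list of class `truth_tables` with tibbles `genes`
#'     (`gene`, `de_flag`, `concord_flag`, `module`), `true_lfc` (`gene`,
#'     `diet`, `tissue`, `lfc`), `batch_offsets`, `sample_depths`.}
#' }
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 50, seed = 7))
#' dim(sim$counts)
#' head(sim$truth$genes)
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  diets <- config$diets
  tissues <- config$tissues
  reps <- config$n_replicates

  meta <- tidyr::expand_grid(
    tissue = tissues, diet = diets, replicate = seq_len(reps)
  ) |>
    dplyr::mutate(
      batch = .data$replicate,
      sample_id = sprintf("%s_%s_r%d", .data$tissue, .data$diet,
                          .data$replicate)
    ) |>
    dplyr::select("sample_id", "diet", "tissue", "replicate", "batch")
  N <- nrow(meta)
  genes <- sprintf("g%0*d", nchar(G), seq_len(G))

  baseline <- rnorm(G, config$baseline_logmean_mu,
                    config$baseline_logmean_sigma)
  tissue_eff <- matrix(rnorm(G * length(tissues), 0, config$tissue_effect_sd),
                       G, length(tissues), dimnames = list(genes, tissues))

  # Planted diet effects relative to the reference (first) diet. The
  # concordance fraction is constructed exactly: among DE genes, the first
  # round(rho * n_de) of a random ordering get matching signs for the two
  # non-reference diets, the rest opposite signs.
  n_de <- round(config$pi_de * G)
  de_idx <- sample.int(G, n_de)
  de_flag <- logical(G)
  de_flag[de_idx] <- TRUE
  n_alt <- length(diets) - 1L
  if (n_de > 0 && n_alt == 0) {
    stop("diet effects require at least 2 diets", call. = FALSE)
  }
  lfc <- array(0, dim = c(G, n_alt, length(tissues)),
               dimnames = list(genes, diets[-1], tissues))
  concord_flag <- logical(G)
  if (n_de > 0) {
    draw_mag <- function(n) {
      if (!is.null(config$fixed_effect_size)) {
        rep(config$fixed_effect_size, n)
      } else {
        abs(rnorm(n, 0, config$effect_size_sd))
      }
    }
    base_eff <- matrix(0, n_de, n_alt)
    sign1 <- sample(c(-1, 1), n_de, replace = TRUE)
    base_eff[, 1] <- sign1 * draw_mag(n_de)
    if (n_alt >= 2) {
      n_con <- round(config$rho_concord * n_de)
      con <- c(rep(TRUE, n_con), rep(FALSE, n_de - n_con))
      concord_flag[de_idx] <- con
      base_eff[, 2] <- ifelse(con, sign1, -sign1) * draw_mag(n_de)
      if (n_alt > 2) {
        for (a in 3:n_alt) {
          base_eff[, a] <- sample(c(-1, 1), n_de, replace = TRUE) *
            draw_mag(n_de)
        }
      }
    }
    # Tissue-specific log-normal perturbation: interaction without sign flips.
    for (a in seq_len(n_alt)) {
      for (t in seq_along(tissues)) {
        lfc[de_idx, a, t] <- base_eff[, a] *
          exp(rnorm(n_de, 0, config$interaction_sd))
      }
    }
  }

  batch_offsets <- rnorm(reps, 0, config$batch_effect_sd)

  module_label <- rep("none", G)
  module_load <- numeric(G)
  module_factor <- matrix(0, G, N)
  if (length(config$module_spec) > 0) {
    sizes <- vapply(config$module_spec, `[`, numeric(1), 1)
    pool <- sample.int(G, sum(sizes))
    offset <- 0L
    for (m in seq_along(config$module_spec)) {
      members <- pool[offset + seq_len(sizes[m])]
      offset <- offset + sizes[m]
      module_label[members] <- sprintf("mod%d", m)
      loading <- abs(rnorm(sizes[m], 0, config$module_spec[[m]][2]))
      module_load[members] <- loading
      f <- rnorm(N)
      module_factor[members, ] <- outer(loading, f)
    }
  }

  depth <- exp(runif(N, log(config$library_size_range[1]),
                     log(config$library_size_range[2])))

  diet_idx <- match(meta$diet, diets) - 1L    # 0 = reference
  tissue_idx <- match(meta$tissue, tissues)
  log2mu <- matrix(baseline, G, N) + tissue_eff[, tissue_idx, drop = FALSE]
  for (j in seq_len(N)) {
    if (diet_idx[j] > 0) log2mu[, j] <- log2mu[, j] + lfc[, diet_idx[j], tissue_idx[j]]
    log2mu[, j] <- log2mu[, j] + batch_offsets[meta$batch[j]]
  }
  log2mu <- log2mu + module_factor
  # numerical guard: cap expected counts at 2^28 so NB draws stay within
  # integer range even in extreme latent-factor tails
  log2mu <- pmin(log2mu, 28)
  mu <- sweep(2^log2mu, 2, depth, `*`)
  counts <- matrix(rnbinom(G * N, mu = mu, size = 1 / config$dispersion),
                   G, N, dimnames = list(genes, meta$sample_id))
  storage.mode(counts) <- "integer"

  true_lfc <- tidyr::expand_grid(gene = genes, diet = diets,
                                 tissue = tissues) |>
    dplyr::mutate(lfc = purrr::pmap_dbl(
      list(.data$gene, .data$diet, .data$tissue),
      function(g, d, t) if (d == diets[1]) 0 else lfc[g, d, t]
    ))

  truth <- structure(
    list(
      genes = tibble::tibble(gene = genes, de_flag = de_flag,
                             concord_flag = concord_flag,
                             module = module_label),
      true_lfc = true_lfc,
      batch_offsets = tibble::tibble(batch = seq_len(reps),
                                     offset = batch_offsets),
      sample_depths = tibble::tibble(sample_id = meta$sample_id,
                                     depth = depth)
    ),
    class = "truth_tables"
  )

  structure(list(counts = counts, meta = meta, truth = truth,
                 config = config),
            class = "diet_sim")
}

#' Write / read planted simulation truth tables
#'
#' `write_truth()` serializes the ground-truth tables of a simulation to
#' four TSV files in `dir` (`truth_genes.tsv`, `truth_lfc.tsv`,
#' `truth_batch.tsv`, `truth_depths.tsv`); `read_truth()` restores them.
#' The round trip is lossless.
#'
#' @param truth a `truth_tables` object from [simulate_counts()].
#' @param dir directory to write into (created if missing).
#' @return `write_truth()` the paths written, invisibly; `read_truth()` a
#'   `truth_tables` object.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "truth_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("truth_genes.tsv", "truth_lfc.tsv",
                            "truth_batch.tsv", "truth_depths.tsv"))
  readr::write_tsv(truth$genes, paths[1])
  readr::write_tsv(truth$true_lfc, paths[2])
  readr::write_tsv(truth$batch_offsets, paths[3])
  readr::write_tsv(truth$sample_depths, paths[4])
  invisible(paths)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  rd <- function(f, types) {
    readr::read_tsv(file.path(dir, f), col_types = types, progress = FALSE)
  }
  structure(
    list(
      genes = rd("truth_genes.tsv", "cllc"),
      true_lfc = rd("truth_lfc.tsv", "cccd"),
      batch_offsets = rd("truth_batch.tsv", "id"),
      sample_depths = rd("truth_depths.tsv", "cd")
    ),
    class = "truth_tables"
  )
}
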