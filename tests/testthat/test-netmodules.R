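test_that("signed adjacency maps correlation into [0, 1] as specified", {
  # exact correlations +1, -1, 0 by construction
  up <- c(1, 2, 3, 4)
  expr <- rbind(a = up, b = 2 * up + 1, c = rev(up),
                d = c(1, -1, 1, -1) + 2.5)
  A <- signed_adjacency(expr, power = 2)
  expect_equal(A["a", "b"], 1)            # cor  1 -> 1
  expect_equal(A["a", "c"], 0)            # cor -1 -> 0
  expect_equal(A["a", "a"], 1)
  e <- rbind(x = c(1, -1, 1, -1), y = c(1, 1, -1, -1))
  expect_equal(signed_adjacency(e, power = 2)["x", "y"], 0.25)  # cor 0
  expect_true(isSymmetric(A))
  # constant gene treated as uncorrelated, with a message
  expect_message(Ac <- signed_adjacency(rbind(k = rep(2, 4), a = up), 6),
                 "constant")
  expect_equal(Ac["k", "a"], 0.5^6)
})

test_that("TOM matches the hand formula and the triple-loop oracle", {
  A3 <- matrix(0.5, 3, 3); diag(A3) <- 1
  tom3 <- topological_overlap(A3)
  expect_equal(tom3[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5))  # = 0.5
  expect_equal(unname(diag(tom3)), rep(1, 3))
  # no edges -> no overlap
  expect_equal(strip_attrs(topological_overlap(diag(4))), diag(4))
  set.seed(3)
  for (i in 1:5) {
    n <- sample(5:15, 1)
    C <- cor(matrix(rnorm(n * 20), 20, n))
    A <- ((1 + C) / 2)^4; diag(A) <- 1
    expect_equal(strip_attrs(topological_overlap(A)), tom_oracle(A),
                 tolerance = 1e-12)
  }
  expect_error(topological_overlap(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("scale-free fit is high for an exact power law, degenerate otherwise", {
  # Pareto-distributed connectivities: density ~ k^-2.5, log-log linear
  set.seed(1)
  k <- runif(3000)^(-1 / 1.5)
  expect_gt(scale_free_fit(k), 0.95)
  # a rising degree density gets a negative sign
  expect_lt(scale_free_fit(2 - runif(3000)^(-1 / 8)), 0)
  expect_warning(out <- scale_free_fit(rep(3, 50)), "degenerate")
  expect_true(is.na(out))
})

test_that("soft-threshold selection returns the requested single candidate", {
  set.seed(9)
  expr <- matrix(rnorm(60 * 10), 60, 10)
  st <- suppressWarnings(pick_soft_threshold(expr, powers = 23))
  expect_s3_class(st, "soft_threshold")
  expect_equal(st$power, 23)
  expect_equal(nrow(st$fits), 1)
  # i.i.d. noise never reaches the 0.90 target across a candidate grid
  expect_warning(pick_soft_threshold(expr, powers = c(2, 6, 23)),
                 "best fit")
})

test_that("static cut recovers separable blocks and drops small ones", {
  set.seed(21)
  n_s <- 40
  block_profile <- function(n_genes) {
    f <- rnorm(n_s)
    t(replicate(n_genes, f + rnorm(n_s, sd = 0.15)))
  }
  expr <- rbind(block_profile(40), block_profile(40), block_profile(8))
  rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  A <- signed_adjacency(expr, power = 8)
  tom <- topological_overlap(A)
  cc <- cluster_and_cut(tom, cut_height = 0.95, min_size = 30)
  asg <- cc$assignment
  expect_setequal(unique(asg$module[1:80]), c("M1", "M2"))
  expect_equal(length(unique(asg$module[1:40])), 1)
  expect_equal(length(unique(asg$module[41:80])), 1)
  # the 8-gene block is below min_size -> unassigned
  expect_true(all(asg$module[81:88] == "unassigned"))
})

test_that("dendrogram heights equal a naive average-linkage oracle", {
  set.seed(5)
  x <- matrix(rnorm(36), 6, 6)
  d <- as.matrix(dist(x))
  tom_like <- 1 - d / max(d)   # similarity in [0, 1]
  diag(tom_like) <- 1
  cc <- cluster_and_cut(tom_like, cut_height = 0.5, min_size = 2)
  expect_equal(cc$dendrogram$height,
               avg_linkage_heights(1 - tom_like), tolerance = 1e-12)
})

test_that("module eigengene is the oriented first PC of standardized members", {
  n_s <- 12
  v <- rnorm(n_s)
  expr <- rbind(a = 2 * v + 3, b = -5 * v, c = 0.5 * v - 1)
  me <- module_eigengene(expr, c("a", "b", "c"))
  expect_equal(me$var_explained, 1, tolerance = 1e-12)
  expect_equal(sum(me$eigengene^2), 1, tolerance = 1e-12)
  # orientation: non-negative correlation with the mean standardized profile
  S <- t(scale(t(expr)))
  expect_gte(cor(me$eigengene, colMeans(S)), 0)

  # two opposite members: variance explained 1, deterministic sign
  me2 <- module_eigengene(rbind(a = v, b = -v), c("a", "b"))
  expect_equal(me2$var_explained, 1, tolerance = 1e-12)
  expect_gt(me2$eigengene[which.max(abs(me2$eigengene))], 0)

  expect_error(module_eigengene(rbind(a = rep(1, 5), b = rep(2, 5)),
                                c("a", "b")),
               "constant")
})

test_that("eigengene matches an independent SVD oracle", {
  set.seed(31)
  expr <- matrix(rnorm(4 * 9), 4, 9,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:9)))
  me <- module_eigengene(expr, rownames(expr))
  S <- t(scale(t(expr)))
  ev <- eigen(crossprod(S))
  expect_equal(abs(unname(me$eigengene)), abs(ev$vectors[, 1]),
               tolerance = 1e-10)
  expect_equal(me$var_explained, ev$values[1] / sum(ev$values),
               tolerance = 1e-10)
})

test_that("negating one member leaves the eigengene invariant up to orientation", {
  set.seed(12)
  expr <- matrix(rnorm(5 * 10), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  e1 <- module_eigengene(expr, rownames(expr))$eigengene
  flipped <- expr
  flipped["g3", ] <- -flipped["g3", ]
  e2 <- module_eigengene(flipped, rownames(flipped))$eigengene
  expect_equal(abs(e1), abs(e2), tolerance = 1e-10)
})

test_that("module merging is iterative, thresholded, and order independent", {
  set.seed(7)
  n_s <- 30
  f1 <- rnorm(n_s); f2 <- rnorm(n_s)
  near_dup <- function(f, n, sd) t(replicate(n, f + rnorm(n_s, sd = sd)))
  expr <- rbind(near_dup(f1, 10, 0.1),   # A
                near_dup(f1, 10, 0.1),   # B: duplicate of A
                near_dup(f2, 10, 0.1))   # C: independent
  rownames(expr) <- paste0("g", 1:30)
  asg <- tibble::tibble(gene = rownames(expr),
                        module = rep(c("A", "B", "C"), each = 10))
  merged <- merge_similar_modules(expr, asg, threshold = 0.9)
  expect_setequal(unique(merged$module), c("A", "C"))  # keeps smaller label

  # orthogonal eigengenes: nothing merges
  asg2 <- tibble::tibble(gene = rownames(expr),
                         module = rep(c("A", "C"), c(20, 10)))
  expect_identical(merge_similar_modules(expr, asg2, 0.9), asg2)

  # chain: three near-identical modules collapse to one
  expr3 <- rbind(near_dup(f1, 8, 0.05), near_dup(f1, 8, 0.05),
                 near_dup(f1, 8, 0.05))
  rownames(expr3) <- paste0("h", 1:24)
  asg3 <- tibble::tibble(gene = rownames(expr3),
                         module = rep(c("x", "y", "z"), each = 8))
  m3 <- merge_similar_modules(expr3, asg3, 0.9)
  expect_equal(length(unique(m3$module)), 1)

  # relabelling modules does not change the final partition
  relab <- c(A = "Q", B = "P", C = "R")
  asg_r <- dplyr::mutate(asg, module = relab[module])
  merged_r <- merge_similar_modules(expr, asg_r, threshold = 0.9)
  part <- function(a) unname(split(a$gene, a$module))
  expect_setequal(lapply(part(merged), sort), lapply(part(merged_r), sort))

  # unassigned never merges
  asg_u <- dplyr::mutate(asg, module = ifelse(module == "B", "unassigned",
                                              module))
  m_u <- merge_similar_modules(expr, asg_u, 0.9)
  expect_equal(sum(m_u$module == "unassigned"), 10)
})

test_that("resampling robustness respects its contracts on a small case", {
  sim <- simulate_counts(sim_config(
    n_genes = 120, tissues = "B", tissue_effect_sd = 0, pi_de = 0,
    baseline_logmean_mu = 7, baseline_logmean_sigma = 1,
    module_spec = list(c(40, 4), c(40, 4)), seed = 14))
  e <- shifted_log_transform(sim$counts,
                             estimate_size_factors(sim$counts))
  fit <- detect_modules(e, min_size = 25)
  rob <- resample_robustness(e, sim$meta, fit, resamples = 15, kept = 4,
                             seed = 6)
  sup <- rob$support$support
  expect_true(all(is.na(sup) | (sup >= 0 & sup <= 1)))
  expect_true(all(is.na(sup[rob$support$module == "unassigned"])))
  full_labels <- unique(fit$assignment$module)
  expect_true(all(rob$assignment$module %in% full_labels))
  # genes dropping below the support threshold are unassigned
  low <- !is.na(sup) & sup < 0.5
  expect_true(all(rob$assignment$module[low] == "unassigned"))
  expect_error(resample_robustness(e, sim$meta, fit, resamples = 2,
                                   kept = 7),
               "exceeds")
})

test_that("eigengene ANOVA separates tissue from diet signal and needs balance", {
  meta <- tidyr::expand_grid(tissue = c("B", "H", "O"),
                             diet = c("C", "DR", "HS"),
                             replicate = 1:6) |>
    dplyr::mutate(sample_id = paste(tissue, diet, replicate, sep = "_"))
  set.seed(3)
  e_tissue <- as.numeric(meta$tissue == "O") + rnorm(54, sd = 0.1)
  eg <- rbind(m1 = e_tissue / sqrt(sum(e_tissue^2)))
  colnames(eg) <- meta$sample_id
  out <- eigengene_anova(eg, meta)
  expect_setequal(out$term, c("diet", "tissue", "diet:tissue"))
  expect_lt(out$p[out$term == "tissue"], 1e-10)
  expect_lt(out$p[out$term == "tissue"], out$p[out$term == "diet"])
  expect_true(all(out$p_adj >= out$p))
  expect_error(eigengene_anova(eg, meta[c(1:53, 1), ]) , "balanced")
})

test_that("planted diet shifts dominate eigengene ANOVA p-values", {
  meta <- tidyr::expand_grid(tissue = "B", diet = c("C", "DR", "HS"),
                             replicate = 1:6) |>
    dplyr::mutate(sample_id = paste(diet, replicate, sep = "_"))
  set.seed(8)
  hits <- vapply(1:40, function(i) {
    e <- as.numeric(meta$diet == "DR") + rnorm(18, sd = 0.1)
    eg <- rbind(m = e); colnames(eg) <- meta$sample_id
    eigengene_anova(eg, meta)$p[1] < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
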