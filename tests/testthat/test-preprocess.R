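test_that("size factors match the median-of-ratios hand calculation", {
  m <- cbind(s1 = c(10, 30, 5), s2 = c(20, 60, 10))
  expect_equal(unname(estimate_size_factors(m)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  ident <- cbind(a = c(4, 9, 2), b = c(4, 9, 2), c = c(4, 9, 2))
  expect_equal(unname(estimate_size_factors(ident)), rep(1, 3))
})

test_that("size factors recover depth ratios on proportional columns", {
  set.seed(7)
  base <- rnbinom(50, mu = 50, size = 5) + 1
  scales <- c(0.5, 1, 2, 4)
  m <- outer(base, scales)
  sf <- estimate_size_factors(m)
  expect_equal(sf / sf[2], scales / scales[2], tolerance = 1e-12)
})

test_that("size factors error when no gene is positive everywhere", {
  m <- cbind(c(0, 5), c(5, 0))
  expect_error(estimate_size_factors(m), "degenerate")
})

test_that("count filter keeps boundary genes and drops singletons", {
  m <- rbind(boundary = c(10, 10, 0, 0),
             spike = c(1000, 0, 0, 0),
             strong = c(50, 60, 70, 80))
  f <- filter_low_counts(m, min_count = 10, min_samples = 2)
  expect_identical(rownames(f), c("boundary", "strong"))
  expect_warning(filter_low_counts(matrix(0, 3, 4)), "every gene")
  expect_identical(filter_low_counts(f), f)  # idempotent
})

test_that("variance filter uses the unbiased variance", {
  m <- rbind(flat = c(3, 3, 3), edge = c(0, 2, 1), keep = c(0, 5, 10))
  f <- filter_low_variance(m, threshold = 1)
  expect_identical(rownames(f), c("edge", "keep"))  # var(0,2,1) = 1
  expect_equal(var(c(0, 2)), 2)
  expect_identical(rownames(filter_low_variance(rbind(c(0, 2)), 1)), NULL)
  expect_equal(nrow(filter_low_variance(m, threshold = 0)), 3)
  expect_identical(filter_low_variance(f, 1), f)
})

test_that("shifted log transform matches hand arithmetic and is scale invariant", {
  m <- rbind(g = c(0, 15))
  out <- shifted_log_transform(m, c(1, 1.5))
  expect_equal(unname(out["g", 1]), 0)
  expect_equal(unname(out["g", 2]), log2(11), tolerance = 1e-12)
  out2 <- shifted_log_transform(rbind(g = c(0, 30)), c(1, 3))
  expect_equal(strip_attrs(out2), strip_attrs(out))
  expect_error(shifted_log_transform(m, c(1, 1), pseudocount = 0),
               "positive")
  expect_identical(attr(out, "provenance"), "shifted-log")
})

make_meta <- function(n_per_cell = 2, diets = c("C", "DR"),
                      tissues = c("B", "H")) {
  tidyr::expand_grid(tissue = tissues, diet = diets,
                     replicate = seq_len(n_per_cell)) |>
    dplyr::mutate(batch = replicate,
                  sample_id = paste(tissue, diet, replicate, sep = "_"))
}

test_that("residual PCA recovers a planted hidden factor", {
  set.seed(42)
  meta <- make_meta(n_per_cell = 6)
  n <- nrow(meta)
  G <- 200
  expr <- matrix(rnorm(G * n, sd = 0.3), G, n,
                 dimnames = list(paste0("g", 1:G), meta$sample_id))
  expr <- expr + outer(rnorm(G, 5, 1), rep(1, n))  # baselines
  # hidden factor orthogonal to the known design (a genuinely latent axis)
  X <- model.matrix(~ diet + tissue + factor(batch), meta)
  h <- rnorm(n)
  h <- drop(h - X %*% solve(crossprod(X), crossprod(X, h)))
  h <- h / sd(h)
  affected <- 1:60  # 30% of genes
  expr[affected, ] <- expr[affected, ] + outer(runif(60, 0.5, 1.5), h)
  di <- estimate_surrogate_variable(expr, meta)
  expect_true(di$sv_defined)
  expect_equal(mean(di$sv), 0, tolerance = 1e-12)
  expect_equal(sum(di$sv^2), 1, tolerance = 1e-12)
  expect_gte(abs(cor(di$sv, h)), 0.9)

  # permuting the samples permutes the SV identically
  perm <- sample(n)
  di_p <- estimate_surrogate_variable(expr[, perm],
                                      meta[perm, , drop = FALSE])
  expect_equal(di_p$sv, di$sv[perm], tolerance = 1e-8)
})

test_that("zero residuals yield a zero surrogate variable with a warning", {
  meta <- make_meta(n_per_cell = 3)
  X <- model.matrix(~ diet + tissue + factor(batch), meta)
  B <- matrix(rnorm(5 * ncol(X)), 5, ncol(X))
  expr <- B %*% t(X)
  colnames(expr) <- meta$sample_id
  expect_warning(di <- estimate_surrogate_variable(expr, meta),
                 "undefined")
  expect_true(all(di$sv == 0))
})

test_that("batch removal erases an additive batch offset exactly", {
  meta <- make_meta(n_per_cell = 4, tissues = "B")
  meta$batch <- rep(1:2, each = 2) |> rep(times = 2)
  n <- nrow(meta)
  expr <- matrix(5, 10, n, dimnames = list(paste0("g", 1:10),
                                           meta$sample_id))
  delta <- 2.5
  expr[, meta$batch == 2] <- expr[, meta$batch == 2] + delta
  di <- suppressWarnings(
    estimate_surrogate_variable(expr, meta, protected = "diet"))
  out <- remove_batch_effects(expr, di)
  b1 <- rowMeans(out[, meta$batch == 1])
  b2 <- rowMeans(out[, meta$batch == 2])
  expect_equal(b1, b2, tolerance = 1e-10)
  expect_identical(dimnames(out), dimnames(expr))
})

test_that("protected diet structure passes through batch removal untouched", {
  meta <- make_meta(n_per_cell = 4, tissues = "B")
  n <- nrow(meta)
  set.seed(1)
  expr <- outer(rnorm(20, 5, 1), rep(1, n)) +
    outer(rnorm(20, 0, 1), as.numeric(meta$diet == "DR"))
  dimnames(expr) <- list(paste0("g", 1:20), meta$sample_id)
  di <- suppressWarnings(
    estimate_surrogate_variable(expr, meta, protected = "diet"))
  out <- remove_batch_effects(expr, di)
  expect_equal(strip_attrs(out), strip_attrs(expr), tolerance = 1e-10)
})

test_that("batch removal matches a joint least-squares oracle", {
  set.seed(11)
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    diet = rep(c("C", "DR"), 3),
    batch = rep(1:2, each = 3)
  )
  expr <- matrix(rnorm(5 * 6, 4, 2), 5, 6,
                 dimnames = list(paste0("g", 1:5), meta$sample_id))
  sv <- scale(rnorm(6))[, 1]
  sv <- sv / sqrt(sum(sv^2))
  di <- structure(list(
    sv = stats::setNames(sv, meta$sample_id),
    batch = factor(meta$batch),
    protected = data.frame(diet = factor(meta$diet)),
    sv_defined = TRUE
  ), class = "design_info")
  out <- remove_batch_effects(expr, di)

  # oracle: per gene, solve the joint normal equations with sum-to-zero
  # batch contrasts and subtract the batch + SV components only
  Xp <- model.matrix(~ diet, data.frame(diet = factor(meta$diet)))
  bf <- factor(meta$batch)
  contrasts(bf) <- contr.sum(2)
  Xb <- model.matrix(~ bf)[, -1, drop = FALSE]
  X <- cbind(Xp, Xb, sv = sv)
  expected <- t(apply(expr, 1, function(y) {
    beta <- solve(crossprod(X), crossprod(X, y))
    y - drop(cbind(Xb, sv) %*% beta[(ncol(Xp) + 1):ncol(X)])
  }))
  expect_equal(strip_attrs(out), strip_attrs(expected), tolerance = 1e-8)
})

test_that("confounded batch is rejected", {
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    diet = rep(c("C", "DR"), each = 3),
    batch = rep(1:2, each = 3)   # identical to diet
  )
  expr <- matrix(rnorm(12), 2, 6,
                 dimnames = list(c("g1", "g2"), meta$sample_id))
  di <- structure(list(
    sv = rep(0, 6), batch = factor(meta$batch),
    protected = data.frame(diet = factor(meta$diet)), sv_defined = FALSE
  ), class = "design_info")
  expect_error(remove_batch_effects(expr, di), "confounded")
})
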