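#' Read and write GMT gene-set collections
#'
#' GMT is tab-separated: set name, description, then member gene ids.
#' `read_gmt()` returns a tibble with a list-column of members;
#' `write_gmt()` inverts it.
#'
#' @param path file path.
#' @param collection tibble with columns `set_name`, `description`,
#'   `genes` (list of character vectors).
#' @return `read_gmt()`: the collection tibble.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1], call. = FALSE)
  out <- tibble::tibble(
    set_name = vapply(parts, `[`, character(1), 1),
    description = vapply(parts, `[`, character(1), 2),
    genes = lapply(parts, function(p) p[-(1:2)])
  )
  if (anyDuplicated(out$set_name)) {
    stop("duplicate set names in GMT", call. = FALSE)
  }
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(collection, function(set_name, description,
                                                genes, ...) {
    paste(c(set_name, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Build a synthetic gene-set collection
#'
#' Random sets drawn from a gene universe, used in place of curated
#' pathway databases for testing and simulation studies.
#'
#' @param genes gene universe.
#' @param n_sets number of sets.
#' @param size_range inclusive range of set sizes.
#' @param seed integer seed.
#' @return a collection tibble as from [read_gmt()].
#' @export
make_synthetic_collection <- function(genes, n_sets = 25,
                                      size_range = c(10, 50), seed = 1L) {
  set.seed(seed)
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  tibble::tibble(
    set_name = sprintf("set%02d", seq_len(n_sets)),
    description = "synthetic",
    genes = lapply(sizes, function(s) sample(genes, s))
  )
}

#' Two-sample t-test of a gene set against the background
#'
#' Welch two-sample t-test of the per-gene statistic (typically the log2
#' fold change) for genes in the set versus all background genes outside
#' it, reporting `mean_change = mean(set) - mean(rest)`. Invariant under
#' uniform translation of the statistics.
#'
#' @param stats named numeric vector, gene -> statistic.
#' @param set_genes member gene ids of the set.
#' @param background background gene ids (default: all of
#'   `names(stats)`).
#' @param min_size minimum size of both the intersected set and the rest.
#' @param alternative passed to [stats::t.test()].
#' @return one-row tibble: `n_set`, `mean_change`, `statistic`, `p`.
#' @export
set_t_test <- function(stats, set_genes, background = names(stats),
                       min_size = 10, alternative = "two.sided") {
  bg <- intersect(background, names(stats))
  in_set <- intersect(set_genes, bg)
  rest <- setdiff(bg, in_set)
  if (length(in_set) < min_size || length(rest) < min_size) {
    stop("undersized set (need >= ", min_size,
         " genes in the set and in the rest)", call. = FALSE)
  }
  x <- stats[in_set]; y <- stats[rest]
  tt <- t.test(x, y, alternative = alternative)
  tibble::tibble(n_set = length(in_set),
                 mean_change = mean(x) - mean(y),
                 statistic = unname(tt$statistic),
                 p = tt$p.value)
}

#' Fisher-exact over-representation of a module in a gene set
#'
#' One-sided (over-representation) hypergeometric tail probability for
#' the 2x2 table of module membership by set membership over the
#' background.
#'
#' @param member_genes module gene list (must be a subset of
#'   `background`).
#' @param set_genes gene set.
#' @param background background gene universe.
#' @return one-row tibble: `n_set`, `n_members`, `overlap`, `p`.
#' @export
fisher_enrichment <- function(member_genes, set_genes, background) {
  if (length(background) == 0) stop("empty background", call. = FALSE)
  if (!all(member_genes %in% background)) {
    stop("member genes must be a subset of the background", call. = FALSE)
  }
  set_bg <- intersect(set_genes, background)
  a <- length(intersect(member_genes, set_bg))
  p <- phyper(a - 1, length(set_bg),
              length(background) - length(set_bg),
              length(member_genes), lower.tail = FALSE)
  tibble::tibble(n_set = length(set_bg), n_members = length(member_genes),
                 overlap = a, p = p)
}

#' Set-level analysis over a gene-set collection
#'
#' Runs either the two-sample t-test of per-gene statistics
#' (`mode = "ttest"`, Benjamini-Hochberg adjustment) or Fisher-exact
#' over-representation of a gene list (`mode = "fisher"`, Bonferroni
#' adjustment) for every eligible set in the collection, returning
#' results sorted by adjusted p-value. Undersized sets are skipped with
#' a message; if no set is eligible an empty tibble is returned with a
#' warning.
#'
#' @param x for `"ttest"`: a named numeric vector of per-gene statistics
#'   or a tibble with `gene` and a statistic column; for `"fisher"`: a
#'   character vector of member genes (e.g. one module's genes).
#' @param collection a collection tibble ([read_gmt()] /
#'   [make_synthetic_collection()]).
#' @param mode `"ttest"` or `"fisher"`.
#' @param background background universe; defaults to `names(x)` for
#'   `"ttest"` (required for `"fisher"`).
#' @param min_size minimum eligible set size after background
#'   intersection.
#' @param stat_col statistic column used when `x` is a tibble.
#' @param alternative for the t-test.
#' @return tibble: `set_name`, `n_set`, per-mode statistic columns, `p`,
#'   `p_adj`, sorted by `p_adj` then `p`.
#' @export
run_set_analysis <- function(x, collection, mode = c("ttest", "fisher"),
                             background = NULL, min_size = 10,
                             stat_col = "lfc",
                             alternative = "two.sided") {
  mode <- match.arg(mode)
  if (mode == "ttest") {
    if (is.data.frame(x)) {
      x <- stats::setNames(x[[stat_col]], x$gene)
    }
    background <- background %||% names(x)
    rows <- purrr::map(seq_len(nrow(collection)), function(i) {
      res <- tryCatch(
        set_t_test(x, collection$genes[[i]], background,
                   min_size = min_size, alternative = alternative),
        error = function(e) NULL)
      if (is.null(res)) {
        message("skipping undersized set ", collection$set_name[i])
        return(NULL)
      }
      dplyr::mutate(res, set_name = collection$set_name[i], .before = 1)
    })
  } else {
    if (is.null(background)) {
      stop("`background` is required for fisher mode", call. = FALSE)
    }
    rows <- purrr::map(seq_len(nrow(collection)), function(i) {
      set_bg <- intersect(collection$genes[[i]], background)
      if (length(set_bg) < min_size) {
        message("skipping undersized set ", collection$set_name[i])
        return(NULL)
      }
      fisher_enrichment(x, collection$genes[[i]], background) |>
        dplyr::mutate(set_name = collection$set_name[i], .before = 1)
    })
  }
  rows <- purrr::compact(rows)
  if (length(rows) == 0) {
    warning("no eligible sets in the collection", call. = FALSE)
    return(tibble::tibble(set_name = character(0), n_set = integer(0),
                          p = numeric(0), p_adj = numeric(0)))
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- if (mode == "ttest") bh_adjust(out$p) else
    pmin(1, out$p * nrow(out))
  dplyr::arrange(out, .data$p_adj, .data$p)
}
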