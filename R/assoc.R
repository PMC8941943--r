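#' Cross-tabulate homolog presence against biosynthesis category
#'
#' Builds the 2 x k contingency table of genome counts with rows
#' "at least one homolog" / "none" and columns the ordered biosynthesis
#' categories.
#'
#' @param genomes Genome-metadata data.frame with `genome_id` and
#'   `biosynthesis_category` (a factor whose level order is the category
#'   order, or a character vector combined with `category_order`).
#' @param calls A [call_homologs()] result, or a named per-genome paralog
#'   count vector as produced by [summarize_panel()].
#' @param category_order Optional character vector fixing the column order
#'   when `biosynthesis_category` is not a factor.
#' @return Integer matrix (2 x k) with dimnames; total equals the number of
#'   genomes.
#' @export
build_contingency <- function(genomes, calls, category_order = NULL) {
  cat_raw <- genomes$biosynthesis_category
  if (any(is.na(cat_raw)) || any(as.character(cat_raw) == "")) {
    stop("every genome needs a biosynthesis category label")
  }
  lev <- if (is.factor(cat_raw)) levels(cat_raw)
         else category_order %||% sort(unique(as.character(cat_raw)))
  cat_f <- factor(as.character(cat_raw), levels = lev)
  if (any(is.na(cat_f))) stop("category label outside category_order")
  counts <- if (is.numeric(calls)) {
    if (is.null(names(calls))) stop("paralog counts must be named")
    v <- calls[genomes$genome_id]
    if (any(is.na(v))) stop("paralog counts missing for some genomes")
    v
  } else {
    as.integer(table(factor(calls$genome_id,
                            levels = genomes$genome_id)))
  }
  present <- factor(ifelse(counts >= 1, "btuh_present", "btuh_absent"),
                    levels = c("btuh_present", "btuh_absent"))
  tab <- table(present, cat_f)
  m <- matrix(as.integer(tab), nrow = 2,
              dimnames = list(presence = rownames(tab),
                              category = colnames(tab)))
  m
}

#' Chi-square test of independence
#'
#' Pearson's chi-square test on an r x c count table with no continuity
#' correction: expected counts are `row_i * col_j / N`, the statistic is
#' `sum((obs - exp)^2 / exp)` and the p-value is the upper tail of the
#' chi-squared distribution with `(r - 1)(c - 1)` degrees of freedom,
#' evaluated via the regularized incomplete gamma function
#' ([chisq_upper_tail()]).
#'
#' @param table Matrix of non-negative counts with positive total and no
#'   all-zero row or column.
#' @return A list of class `"chisq_independence"`: `statistic`, `df`,
#'   `p_value`, `expected`, `observed`.
#' @examples
#' chi_square_independence(matrix(c(20, 10, 10, 20), 2))
#' @export
chi_square_independence <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m)) || any(!is.finite(m))) {
    stop("table must contain non-negative integer counts")
  }
  if (sum(m) <= 0) stop("table total must be positive")
  rs <- rowSums(m)
  cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) {
    stop("untestable table: zero row or column margin")
  }
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  if (df < 1) stop("untestable table: needs at least 2 rows and 2 columns")
  expected <- outer(rs, cs) / sum(m)
  statistic <- sum((m - expected)^2 / expected)
  out <- list(statistic = statistic, df = df,
              p_value = chisq_upper_tail(statistic, df),
              expected = expected, observed = m)
  class(out) <- "chisq_independence"
  out
}

#' @export
print.chisq_independence <- function(x, ...) {
  cat(sprintf("Chi-square test of independence: X-squared = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# all permutations of 1..n as an (n! x n) matrix, lexicographic
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[r + seq_len(nrow(sub)), 1] <- k
    out[r + seq_len(nrow(sub)), -1] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

pearson_cor <- function(a, b) {
  da <- a - mean(a)
  db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

#' Tie-aware Spearman rank correlation
#'
#' Ranks both vectors with average ranks for ties, and computes `rho` as
#' the Pearson correlation of the rank vectors. Two p-value methods are
#' offered: `"t_approx"` (default) computes
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` and takes the two-sided tail of
#' the t distribution with `n - 2` degrees of freedom (via the regularized
#' incomplete beta function); `"permutation"` permutes one vector --
#' exhaustively over all `n!` orderings for `n <= 8`, otherwise by seeded
#' Monte-Carlo sampling -- and counts permutations with `|rho|` at least as
#' extreme.
#'
#' @param x_ordinal,y_counts Equal-length numeric vectors, `n >= 3`,
#'   neither constant.
#' @param method `"t_approx"` or `"permutation"`.
#' @param seed Seed for the sampled permutation p-value.
#' @param n_perm Number of sampled permutations when `n > 8`.
#' @return A list of class `"spearman_cor"`: `rho`, `n`, `p_value`,
#'   `method`.
#' @examples
#' spearman_rank(c(1, 2, 3), c(2, 4, 6))$rho   # 1
#' @export
spearman_rank <- function(x_ordinal, y_counts,
                          method = c("t_approx", "permutation"),
                          seed = 1, n_perm = 10000) {
  method <- match.arg(method)
  x <- as.numeric(x_ordinal)
  y <- as.numeric(y_counts)
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("rho undefined for a constant vector")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- pearson_cor(rx, ry)
  p <- if (method == "t_approx") {
    if (abs(rho) >= 1) 0 else {
      t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
      t_two_sided(t_stat, n - 2)
    }
  } else {
    eps <- 1e-12
    if (n <= 8) {
      perms <- all_permutations(n)
      stats_p <- apply(perms, 1, function(ix) abs(pearson_cor(rx, ry[ix])))
      mean(stats_p >= abs(rho) - eps)
    } else {
      hits <- with_seed(seed, {
        sum(vapply(seq_len(n_perm), function(i) {
          abs(pearson_cor(rx, sample(ry))) >= abs(rho) - eps
        }, logical(1)))
      })
      (1 + hits) / (n_perm + 1)
    }
  }
  structure(list(rho = rho, n = n, p_value = p, method = method),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.5f, n = %d, p = %.4g (%s)\n",
              x$rho, x$n, x$p_value, x$method))
  invisible(x)
}

#' Two-sided Spearman p-value from a reported rho and n
#'
#' Consistency utility for printed statistics: applies the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`, two-sided on `n - 2` degrees of
#' freedom, directly to a correlation value.
#'
#' @param rho Rank correlation in \[-1, 1\].
#' @param n Sample size, `n >= 3`.
#' @return Two-sided p-value.
#' @examples
#' spearman_p_from_rho(0.47581, 89)
#' @export
spearman_p_from_rho <- function(rho, n) {
  stop_if_not_scalar_number(rho, "rho", -1, 1)
  stop_if_not_scalar_number(n, "n")
  if (n < 3) stop("need n >= 3")
  if (abs(rho) >= 1) return(0)
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  t_two_sided(t_stat, n - 2)
}

#' Association between biosynthesis category and homolog content
#'
#' Runs both Fig-6-style analyses on a genome panel: the chi-square test of
#' independence on presence/absence across the ordered biosynthesis
#' categories, and the tie-aware Spearman correlation between the category
#' ordinal and the per-genome paralog count. Categories are coded by
#' increasing dependence on transport (least biosynthetically capable
#' last), so a positive `rho` means more homolog copies in genomes that
#' rely more on transport -- i.e. an inverse association with biosynthetic
#' capacity.
#'
#' @param genomes Genome-metadata data.frame (`genome_id`,
#'   `biosynthesis_category`).
#' @param paralog_counts Named per-genome counts (e.g.
#'   `summarize_panel()$paralog_count`) or a data.frame with `genome_id`
#'   and `n_paralogs`.
#' @param category_order Optional explicit category order (least to most
#'   transport-dependent).
#' @param spearman_method,seed Passed to [spearman_rank()].
#' @return A list of class `"panel_association"`: `chi_square`
#'   (a `chisq_independence`), `spearman` (a `spearman_cor`), `n`,
#'   `category_order`, `coding` (a note on the ordinal direction).
#' @export
associate_panel <- function(genomes, paralog_counts, category_order = NULL,
                            spearman_method = "t_approx", seed = 1) {
  if (is.data.frame(paralog_counts)) {
    if (!all(c("genome_id", "n_paralogs") %in% names(paralog_counts))) {
      stop("paralog_counts data.frame needs genome_id and n_paralogs")
    }
    paralog_counts <- stats::setNames(paralog_counts$n_paralogs,
                                      paralog_counts$genome_id)
  }
  v <- paralog_counts[genomes$genome_id]
  if (any(is.na(v))) stop("paralog counts missing for some genomes")
  cat_raw <- genomes$biosynthesis_category
  lev <- if (is.factor(cat_raw)) levels(cat_raw)
         else category_order %||% sort(unique(as.character(cat_raw)))
  ord <- as.integer(factor(as.character(cat_raw), levels = lev))
  if (any(is.na(ord))) stop("category label outside category_order")
  tab <- build_contingency(genomes, v, category_order = lev)
  out <- list(
    chi_square = chi_square_independence(tab),
    spearman = spearman_rank(ord, v, method = spearman_method, seed = seed),
    n = nrow(genomes),
    category_order = lev,
    coding = "categories coded 1..k by increasing dependence on transport"
  )
  class(out) <- "panel_association"
  out
}

#' @export
print.panel_association <- function(x, ...) {
  cat(sprintf("Panel association (n = %d genomes; %s)\n", x$n, x$coding))
  cat("  categories: ", paste(x$category_order, collapse = " < "), "\n",
      sep = "")
  cat("  ")
  print(x$chi_square)
  cat("  ")
  print(x$spearman)
  invisible(x)
}
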