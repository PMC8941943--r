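#' Configuration for the differential-enrichment analysis
#'
#' Bundles the analysis choices of the probe-vs-control enrichment pipeline.
#' The defaults are the classical reading of the published procedure:
#' contaminants and proteins identified by fewer than three peptides are
#' removed, proteins must be observed in all replicates of at least one
#' group, missing values are imputed from a left-censored normal model, the
#' one-sided (probe > control) pooled-variance Student t test is applied,
#' and Benjamini-Hochberg-adjusted p-values below `alpha` define hits.
#'
#' Points the published description leaves open are exposed as switches:
#' `fill` chooses whether the censoring floor is the global minimum observed
#' log2 abundance (`"global"`, default) or each protein's own minimum
#' (`"per_protein"`); `sigma_from` chooses whether the shared imputation SD
#' averages per-protein SDs (`"protein"`, default) or per-sample SDs
#' (`"sample"`); `test_variant` switches between the pooled-variance Student
#' test and Welch's unequal-variance test.
#'
#' @param alpha FDR threshold; hits satisfy adjusted p strictly < `alpha`.
#' @param min_peptides Minimum peptide count to retain a protein.
#' @param test_variant `"student"` (pooled variance) or `"welch"`.
#' @param fill `"global"` or `"per_protein"` censoring floor.
#' @param sigma_from `"protein"` or `"sample"` averaging for the shared
#'   imputation SD.
#' @param seed RNG seed for the imputation draws.
#' @return A list of class `"enrichment_config"`.
#' @export
enrichment_config <- function(alpha = 0.05, min_peptides = 3,
                              test_variant = c("student", "welch"),
                              fill = c("global", "per_protein"),
                              sigma_from = c("protein", "sample"),
                              seed = 1) {
  stop_if_not_scalar_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  stop_if_not_scalar_number(min_peptides, "min_peptides", lo = 1)
  stop_if_not_scalar_number(seed, "seed")
  structure(list(alpha = alpha, min_peptides = as.integer(min_peptides),
                 test_variant = match.arg(test_variant),
                 fill = match.arg(fill), sigma_from = match.arg(sigma_from),
                 seed = as.integer(seed)),
            class = "enrichment_config")
}

#' Filter a quantification table for analysis
#'
#' Retains exactly the proteins that (1) are not contaminant-flagged,
#' (2) have `peptide_count >= min_peptides`, and (3) were observed
#' (intensity > 0) in every replicate of at least one of the two groups.
#' Row order is preserved.
#'
#' @param table A [protein_quant_table()].
#' @param config An [enrichment_config()].
#' @return The filtered `protein_quant` table (possibly with zero rows).
#' @export
filter_proteins <- function(table, config = enrichment_config()) {
  stopifnot(inherits(table, "protein_quant"))
  sg <- attr(table, "sample_groups")
  probe <- names(sg)[sg == "probe"]
  ctrl <- names(sg)[sg == "control"]
  inten <- as.matrix(as.data.frame(table)[, names(sg), drop = FALSE])
  present <- inten > 0
  all_probe <- rowSums(present[, probe, drop = FALSE]) == length(probe)
  all_ctrl <- rowSums(present[, ctrl, drop = FALSE]) == length(ctrl)
  keep <- !table$contaminant &
    table$peptide_count >= config$min_peptides &
    (all_probe | all_ctrl)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_groups") <- sg
  attr(out, "screen_id") <- attr(table, "screen_id")
  class(out) <- class(table)
  out
}

# log2 intensity matrix with NA for missing (0) cells.
log2_matrix <- function(table) {
  sg <- attr(table, "sample_groups")
  m <- as.matrix(as.data.frame(table)[, names(sg), drop = FALSE])
  rownames(m) <- table$protein_id
  m[m == 0] <- NA_real_
  log2(m)
}

#' Impute left-censored missing values
#'
#' Implements the published left-censoring imputation on a log2 intensity
#' matrix (rows = proteins, columns = samples, `NA` = missing):
#'
#' 1. The censoring floor `m` is the minimum observed log2 abundance across
#'    all proteins and samples of the comparison (or each protein's own
#'    minimum when `fill = "per_protein"`).
#' 2. Missing cells are provisionally filled with `m`; each protein's normal
#'    mean `mu_p` is the mean of its filled values.
#' 3. The shared SD `sigma` is the average over proteins of the per-protein
#'    sample SD of the filled values (or the average of per-sample SDs when
#'    `sigma_from = "sample"`).
#' 4. Each originally missing cell is replaced by an independent draw from
#'    Normal(`mu_p`, `sigma`), in row-major order (protein by protein, then
#'    sample by sample) from the seeded generator.
#'
#' Observed cells are never touched, and the same seed reproduces the draws
#' exactly. With `sigma = 0` every imputed cell equals its `mu_p`.
#'
#' @param log2_table Numeric matrix of log2 abundances with `NA` for
#'   missing; every row must have at least one observed value.
#' @param seed RNG seed for the draws.
#' @param fill,sigma_from See [enrichment_config()].
#' @return List with `completed` (the imputed matrix) and `record` (list:
#'   `fill_min`, `sigma`, `mu`, `imputed_cells` data.frame).
#' @examples
#' m <- rbind(P1 = c(10, 11, NA, 10, 5, 5, 6, NA),
#'            P2 = c(8, 8, 8, 8, 7, 7, 7, 7))
#' colnames(m) <- paste0("s", 1:8)
#' impute_missing(m, seed = 1)$record$fill_min   # global minimum = 5
#' @export
impute_missing <- function(log2_table, seed = 1, fill = c("global", "per_protein"),
                           sigma_from = c("protein", "sample")) {
  fill <- match.arg(fill)
  sigma_from <- match.arg(sigma_from)
  m <- as.matrix(log2_table)
  if (!is.numeric(m) || any(is.infinite(m))) {
    stop("log2_table must be a numeric matrix of finite values or NA")
  }
  obs <- !is.na(m)
  if (any(rowSums(obs) == 0)) {
    stop("protein with no observed values in either group; ",
         "run filter_proteins() first")
  }
  filled <- m
  if (fill == "global") {
    fill_min <- min(m[obs])
    filled[!obs] <- fill_min
  } else {
    fill_min <- apply(m, 1, min, na.rm = TRUE)
    idx <- which(!obs, arr.ind = TRUE)
    filled[idx] <- fill_min[idx[, 1]]
  }
  mu <- rowMeans(filled)
  sigma <- if (sigma_from == "protein") {
    mean(apply(filled, 1, stats::sd))
  } else {
    mean(apply(filled, 2, stats::sd))
  }
  completed <- filled
  cells <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(m))) {
      j_miss <- which(!obs[i, ])
      if (length(j_miss)) {
        draws <- stats::rnorm(length(j_miss), mu[i], sigma)
        completed[i, j_miss] <- draws
        cells[[length(cells) + 1L]] <- data.frame(
          protein_id = rep(rownames(m)[i] %||% as.character(i),
                           length(j_miss)),
          sample = colnames(m)[j_miss] %||% as.character(j_miss),
          value = draws, stringsAsFactors = FALSE)
      }
    }
  })
  imputed_cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(protein_id = character(), sample = character(),
               value = numeric(), stringsAsFactors = FALSE)
  rownames(imputed_cells) <- NULL
  list(completed = completed,
       record = list(fill_min = fill_min, sigma = sigma, mu = mu,
                     imputed_cells = imputed_cells))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vectorized row-wise one-sided two-sample t tests (probe > control).
# X: numeric matrix; probe_cols/ctrl_cols: column indices.
t_test_rows <- function(X, probe_cols, ctrl_cols,
                        variant = c("student", "welch")) {
  variant <- match.arg(variant)
  n1 <- length(probe_cols)
  n2 <- length(ctrl_cols)
  m1 <- rowMeans(X[, probe_cols, drop = FALSE])
  m2 <- rowMeans(X[, ctrl_cols, drop = FALSE])
  v1 <- apply(X[, probe_cols, drop = FALSE], 1, stats::var)
  v2 <- apply(X[, ctrl_cols, drop = FALSE], 1, stats::var)
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(X))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t_stat <- (m1 - m2) / se
  # zero-variance convention: equal means -> t = 0, p = 1; otherwise the
  # sign of the mean difference decides p in {0, 1}
  degen <- se == 0
  t_stat[degen & m1 == m2] <- 0
  t_stat[degen & m1 > m2] <- Inf
  t_stat[degen & m1 < m2] <- -Inf
  df[degen | !is.finite(df)] <- n1 + n2 - 2
  p <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    p[i] <- if (t_stat[i] == 0 && degen[i]) 1 else
      t_upper_tail(t_stat[i], df[i])
  }
  list(t_stat = t_stat, df = df, p_raw = p,
       mean_probe = m1, mean_control = m2)
}

#' One-sided (right-tailed) two-sample t test
#'
#' Tests the alternative "probe mean > control mean". The default is the
#' classical pooled-variance Student test (`df = n1 + n2 - 2`); `"welch"`
#' uses the unequal-variance statistic with Satterthwaite degrees of
#' freedom. The p-value is the upper-tail probability of the t distribution
#' at the observed statistic, computed via [t_upper_tail()].
#'
#' When both groups have zero variance, the convention is: equal means give
#' `t = 0, p = 1`; a larger probe mean gives `p = 0`; a smaller probe mean
#' gives `p = 1`.
#'
#' @param probe_values,control_values Numeric vectors, each of length >= 2.
#' @param variant `"student"` or `"welch"`.
#' @return List with `t_stat`, `df` and `p_raw`.
#' @examples
#' right_tailed_t_test(c(3, 4, 5, 6), c(1, 2, 3, 2))$t_stat  # 3.2733
#' @export
right_tailed_t_test <- function(probe_values, control_values,
                                variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(probe_values) < 2 || length(control_values) < 2) {
    stop("need at least 2 values per group")
  }
  if (any(!is.finite(c(probe_values, control_values)))) {
    stop("values must be finite")
  }
  X <- matrix(c(probe_values, control_values), nrow = 1)
  r <- t_test_rows(X, seq_along(probe_values),
                   length(probe_values) + seq_along(control_values), variant)
  list(t_stat = r$t_stat, df = r$df, p_raw = r$p_raw)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' The step-up false-discovery-rate adjustment: with the raw p-values sorted
#' ascending, `adj_(i) = min over j >= i of p_(j) * m / j`, capped at 1, and
#' returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values)) stop("p_values must be numeric")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (m == 0) return(numeric(0))
  o <- order(p_values)
  ranked <- p_values[o] * m / seq_len(m)
  adj_sorted <- pmin(1, rev(cummin(rev(ranked))))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

#' Run the full differential-enrichment screen analysis
#'
#' Composes the pipeline on a quantification table: filter (contaminants,
#' peptide count, replicate presence), log2 transform, left-censored
#' imputation, per-protein right-tailed t test, Benjamini-Hochberg
#' correction over all tested proteins, and significance at adjusted
#' p strictly below `alpha`. Group means and the log2 fold change
#' (probe mean minus control mean) are computed on the post-imputation
#' matrix.
#'
#' @param table A [protein_quant_table()] (raw, unfiltered).
#' @param config An [enrichment_config()].
#' @return A data.frame of class `"abp_screen"`, one row per tested protein,
#'   with columns `protein_id`, `mean_log2_probe`, `mean_log2_control`,
#'   `log2_fc`, `t_stat`, `df`, `p_raw`, `p_adj`, `significant`,
#'   `n_imputed`; the configuration, imputation record, screen id and
#'   filter-stage counts are attached as attributes.
#' @examples
#' sim <- simulate_lfq_screen(lfq_sim_params(n_proteins = 300, seed = 2))
#' res <- run_enrichment_screen(sim$table, enrichment_config(seed = 2))
#' summary(res)
#' @export
run_enrichment_screen <- function(table, config = enrichment_config()) {
  stopifnot(inherits(table, "protein_quant"),
            inherits(config, "enrichment_config"))
  n_input <- nrow(table)
  filtered <- filter_proteins(table, config)
  sg <- attr(filtered, "sample_groups")
  empty <- data.frame(protein_id = character(), mean_log2_probe = numeric(),
                      mean_log2_control = numeric(), log2_fc = numeric(),
                      t_stat = numeric(), df = numeric(), p_raw = numeric(),
                      p_adj = numeric(), significant = logical(),
                      n_imputed = integer(), stringsAsFactors = FALSE)
  if (nrow(filtered) == 0) {
    res <- empty
  } else {
    lm2 <- log2_matrix(filtered)
    imp <- impute_missing(lm2, seed = config$seed, fill = config$fill,
                          sigma_from = config$sigma_from)
    X <- imp$completed
    probe_cols <- which(sg[colnames(X)] == "probe")
    ctrl_cols <- which(sg[colnames(X)] == "control")
    tt <- t_test_rows(X, probe_cols, ctrl_cols, config$test_variant)
    p_adj <- bh_fdr(tt$p_raw)
    res <- data.frame(
      protein_id = filtered$protein_id,
      mean_log2_probe = tt$mean_probe,
      mean_log2_control = tt$mean_control,
      log2_fc = tt$mean_probe - tt$mean_control,
      t_stat = tt$t_stat, df = tt$df, p_raw = tt$p_raw, p_adj = p_adj,
      significant = p_adj < config$alpha,
      n_imputed = as.integer(rowSums(is.na(lm2))),
      stringsAsFactors = FALSE
    )
    attr(res, "imputation") <- imp$record
  }
  rownames(res) <- NULL
  attr(res, "config") <- config
  attr(res, "screen_id") <- attr(table, "screen_id")
  attr(res, "counts") <- c(input = n_input, tested = nrow(res))
  class(res) <- c("abp_screen", "data.frame")
  res
}

#' @export
print.abp_screen <- function(x, ...) {
  cn <- attr(x, "counts")
  cat(sprintf("Enrichment screen '%s': %d proteins in, %d tested, %d significant (p_adj < %g)\n",
              attr(x, "screen_id") %||% "?", cn[["input"]], cn[["tested"]],
              sum(x$significant), attr(x, "config")$alpha))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' @export
summary.abp_screen <- function(object, ...) {
  cfg <- attr(object, "config")
  cn <- attr(object, "counts")
  hits <- object[object$significant, , drop = FALSE]
  hits <- hits[order(hits$p_adj, -hits$log2_fc), , drop = FALSE]
  out <- list(screen_id = attr(object, "screen_id"),
              n_input = unname(cn[["input"]]),
              n_tested = unname(cn[["tested"]]),
              n_significant = nrow(hits), alpha = cfg$alpha,
              test_variant = cfg$test_variant,
              sigma = attr(object, "imputation")$sigma,
              n_imputed_cells = sum(object$n_imputed),
              top_hits = utils::head(hits, 10))
  class(out) <- "summary.abp_screen"
  out
}

#' @export
print.summary.abp_screen <- function(x, ...) {
  cat(sprintf("Enrichment screen '%s'\n", x$screen_id))
  cat(sprintf("  proteins in table : %d\n", x$n_input))
  cat(sprintf("  proteins tested   : %d\n", x$n_tested))
  cat(sprintf("  imputed cells     : %d (sigma = %.4g)\n",
              x$n_imputed_cells, x$sigma %||% NA_real_))
  cat(sprintf("  significant hits  : %d (%s t test, BH p_adj < %g)\n",
              x$n_significant, x$test_variant, x$alpha))
  if (nrow(x$top_hits)) {
    cat("  top hits:\n")
    print(x$top_hits[, c("protein_id", "log2_fc", "p_adj")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Intersect the hit lists of two independent screens
#'
#' Reproduces the two-screen reporting logic: proteins significantly
#' enriched in both independently analyzed screens form the high-confidence
#' set (the main-table layout, with each screen's log2 fold change side by
#' side), and proteins significant in one or both form the union set.
#'
#' @param results_screen1,results_screen2 Results from
#'   [run_enrichment_screen()].
#' @return List with `intersection` and `union` (character vectors of
#'   protein ids, sorted) and `table`, a merged data.frame over the union
#'   with per-screen fold changes and adjusted p-values.
#' @export
intersect_screens <- function(results_screen1, results_screen2) {
  h1 <- results_screen1$protein_id[results_screen1$significant]
  h2 <- results_screen2$protein_id[results_screen2$significant]
  both <- sort(intersect(h1, h2))
  either <- sort(union(h1, h2))
  pick <- function(res, ids, col) {
    res[[col]][match(ids, res$protein_id)]
  }
  tab <- data.frame(
    protein_id = either,
    log2_fc_screen1 = pick(results_screen1, either, "log2_fc"),
    log2_fc_screen2 = pick(results_screen2, either, "log2_fc"),
    p_adj_screen1 = pick(results_screen1, either, "p_adj"),
    p_adj_screen2 = pick(results_screen2, either, "p_adj"),
    in_both = either %in% both,
    stringsAsFactors = FALSE
  )
  list(intersection = both, union = either, table = tab)
}
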