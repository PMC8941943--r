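test_that("quant-table IO applies the proteinGroups dialect conventions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- toy_quant_table()
  write_quant_table(tab, f)
  back <- read_quant_table(f, toy_groups(), screen_id = "toy")
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_identical(attr(back, "sample_groups"), attr(tab, "sample_groups"))
  # "+" flags a contaminant, zero intensity means missing
  expect_true(back$contaminant[back$protein_id == "CONT"])
  expect_equal(back$control_1[back$protein_id == "KEEP2"], 0)
  # a simulated screen round-trips exactly
  sim <- simulate_lfq_screen(lfq_sim_params(n_proteins = 80, seed = 6))
  write_quant_table(sim$table, f)
  back <- read_quant_table(f, attr(sim$table, "sample_groups"))
  expect_equal(as.data.frame(back), as.data.frame(sim$table))

  # missing configured sample column is a format error
  expect_error(read_quant_table(f, c(nope = "probe", toy_groups()[-1])),
               "nope")
  # duplicate protein id is a format error
  dup <- as.data.frame(sim$table)[c(1, 1), ]
  utils::write.table(
    data.frame(check.names = FALSE, "Protein IDs" = dup$protein_id,
               "Peptides" = 5, "Potential contaminant" = "",
               "LFQ intensity probe_1" = 1), f,
    sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(protein_quant_table(dup, attr(sim$table, "sample_groups")),
               "duplicate")
})

test_that("filtering retains exactly the hand-counted protein set", {
  tab <- toy_quant_table()
  kept <- filter_proteins(tab, enrichment_config())
  expect_identical(kept$protein_id, c("KEEP1", "KEEP2", "KEEP3"))
  # the packaged fixture gives the same answer through the reader
  fx <- system.file("extdata", "toy_proteinGroups.tsv",
                    package = "cobascreen")
  kept2 <- filter_proteins(read_quant_table(fx, toy_groups()))
  expect_identical(kept2$protein_id, c("KEEP1", "KEEP2", "KEEP3"))
  # peptide threshold is configurable
  expect_true("LOWPEP" %in%
                filter_proteins(tab, enrichment_config(min_peptides = 1))$protein_id)
  # order preserved, attributes carried
  expect_identical(attr(kept, "sample_groups"), toy_groups())
})

test_that("imputation reproduces the hand-computed floor, means and draws", {
  m <- toy_log2_matrix()
  imp <- impute_missing(m, seed = 7)
  # global observed minimum and min-filled per-protein mean
  expect_equal(imp$record$fill_min, 5)
  expect_equal(unname(imp$record$mu["P1"]), 57 / 8)
  expect_equal(unname(imp$record$mu["P2"]), 7.5)
  # sigma recomputed independently from the min-filled matrix
  filled <- m
  filled[is.na(filled)] <- 5
  expect_equal(imp$record$sigma, mean(apply(filled, 1, sd)))
  # observed cells untouched, exactly the missing cells imputed
  obs <- !is.na(m)
  expect_identical(imp$completed[obs], m[obs])
  expect_equal(nrow(imp$record$imputed_cells), 2)
  expect_identical(imp$record$imputed_cells$protein_id, c("P1", "P1"))
  # draws are Normal(mu_p, sigma) under the seeded stream, row-major
  expected_draws <- withr::with_seed(7, rnorm(2, 57 / 8, imp$record$sigma))
  expect_equal(imp$record$imputed_cells$value, expected_draws)
  # same seed reproduces; different seed does not
  expect_identical(impute_missing(m, seed = 7), imp)
  expect_false(identical(impute_missing(m, seed = 8)$completed,
                         imp$completed))
})

test_that("imputation degenerate and error cases follow the contract", {
  m <- toy_log2_matrix()
  # no missing cells: identity, no draws
  full <- m
  full[is.na(full)] <- 6
  imp <- impute_missing(full, seed = 1)
  expect_identical(imp$completed, full)
  expect_equal(nrow(imp$record$imputed_cells), 0)
  # sigma = 0 (all values identical): imputed cells equal mu exactly,
  # independent of seed
  cm <- matrix(3, 4, 4)
  cm[1, 2] <- NA
  s1 <- impute_missing(cm, seed = 1)
  s2 <- impute_missing(cm, seed = 99)
  expect_equal(s1$record$sigma, 0)
  expect_identical(s1$completed, s2$completed)
  expect_equal(s1$completed[1, 2], 3)
  # a row with no observed value violates the contract
  bad <- m
  bad[1, ] <- NA
  expect_error(impute_missing(bad), "no observed values")
  # per-protein floor switch fills each row from its own minimum
  pp <- impute_missing(m, seed = 2, fill = "per_protein")
  expect_equal(unname(pp$record$fill_min), c(5, 7))
  expect_equal(unname(pp$record$mu["P1"]), 57 / 8)  # P1's own min is 5 too
})

test_that("right-tailed t test matches the closed-form pooled formula", {
  r <- right_tailed_t_test(c(3, 4, 5, 6), c(1, 2, 3, 2))
  expect_equal(r$t_stat, 2.5 / sqrt(7 / 12), tolerance = 1e-10)
  expect_equal(r$t_stat, 3.2733, tolerance = 1e-4)
  expect_equal(r$df, 6)
  # p agrees with an independent t-distribution implementation
  expect_equal(r$p_raw, pt(r$t_stat, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # group swap negates t and complements p (continuous case)
  rs <- right_tailed_t_test(c(1, 2, 3, 2), c(3, 4, 5, 6))
  expect_equal(rs$t_stat, -r$t_stat, tolerance = 1e-12)
  expect_equal(rs$p_raw, 1 - r$p_raw, tolerance = 1e-12)
  # against stats::t.test on random draws, both variants
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(4 + i %% 3)
    b <- rnorm(5, mean = 0.5)
    for (v in c("student", "welch")) {
      ours <- right_tailed_t_test(a, b, variant = v)
      ref <- t.test(a, b, alternative = "greater",
                    var.equal = (v == "student"))
      expect_equal(ours$t_stat, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-8)
      expect_equal(ours$p_raw, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("t-test degenerate conventions and Welch/Student agreement hold", {
  # identical zero-variance groups: t = 0, p = 1
  r <- right_tailed_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_raw, 1)
  # zero variance, probe mean larger: p = 0
  expect_equal(right_tailed_t_test(c(3, 3), c(1, 1))$p_raw, 0)
  expect_equal(right_tailed_t_test(c(1, 1), c(3, 3))$p_raw, 1)
  # equal group sizes and variances: Welch reduces to Student
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)  # same variance as a
  st <- right_tailed_t_test(a, b, "student")
  we <- right_tailed_t_test(a, b, "welch")
  expect_equal(we$t_stat, st$t_stat, tolerance = 1e-12)
  expect_equal(we$df, st$df, tolerance = 1e-12)
  expect_error(right_tailed_t_test(1, c(1, 2)), "at least 2")
})

test_that("BH adjustment follows the step-up rule and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, NA)), "\\[0, 1\\]")
  set.seed(17)
  for (i in 1:25) {
    p <- runif(sample(1:60, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_naive(p))
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    # monotone non-decreasing in sorted raw-p order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    # order equivariance
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), adj[perm])
  }
})

test_that("the pipeline equals the manual composition of its stages", {
  sim <- simulate_lfq_screen(lfq_sim_params(n_proteins = 120, seed = 13))
  cfg <- enrichment_config(seed = 13)
  res <- run_enrichment_screen(sim$table, cfg)

  kept <- filter_proteins(sim$table, cfg)
  m <- log2(as.matrix(as.data.frame(kept)[, names(toy_groups())]))
  m[is.infinite(m)] <- NA
  rownames(m) <- kept$protein_id
  imp <- impute_missing(m, seed = cfg$seed)
  manual_p <- vapply(seq_len(nrow(m)), function(i) {
    right_tailed_t_test(imp$completed[i, 1:4], imp$completed[i, 5:8])$p_raw
  }, numeric(1))
  expect_equal(res$protein_id, kept$protein_id)
  expect_equal(res$p_raw, manual_p, tolerance = 1e-12)
  expect_equal(res$p_adj, bh_fdr(manual_p), tolerance = 1e-12)
  expect_identical(res$significant, res$p_adj < cfg$alpha)
  # fold change is exactly the difference of post-imputation group means
  expect_equal(res$log2_fc, res$mean_log2_probe - res$mean_log2_control)
  expect_equal(res$mean_log2_probe,
               unname(rowMeans(imp$completed[, 1:4])), tolerance = 1e-12)
  expect_equal(res$n_imputed, unname(as.integer(rowSums(is.na(m)))))
  # full determinism of the composed pipeline
  expect_identical(res, run_enrichment_screen(sim$table, cfg))
})

test_that("screen intersection implements the two-screen reporting logic", {
  mk <- function(ids, sig, fc) {
    structure(data.frame(protein_id = ids, log2_fc = fc,
                         p_adj = ifelse(sig, 0.01, 0.5),
                         significant = sig, stringsAsFactors = FALSE),
              class = c("abp_screen", "data.frame"))
  }
  r1 <- mk(c("A", "B", "C"), c(TRUE, TRUE, FALSE), c(3, 2, 0.1))
  r2 <- mk(c("B", "C", "D"), c(TRUE, FALSE, TRUE), c(2.5, 0.2, 4))
  out <- intersect_screens(r1, r2)
  expect_identical(out$intersection, "B")
  expect_setequal(out$union, c("A", "B", "D"))
  expect_equal(out$table$log2_fc_screen1[out$table$protein_id == "B"], 2)
  expect_equal(out$table$log2_fc_screen2[out$table$protein_id == "B"], 2.5)
  expect_true(is.na(out$table$log2_fc_screen2[out$table$protein_id == "A"]))
  # identical lists: intersection = union
  out2 <- intersect_screens(r1, r1)
  expect_identical(out2$intersection, out2$union)

  # paired planted screens: the intersection is at least as precise as
  # either screen alone
  p <- lfq_sim_params(n_proteins = 400, n_enriched = 30, effect_log2 = 2,
                      rep_sd = 1, seed = 101)
  s1 <- simulate_lfq_screen(p, "screen1", noise_seed = 201)
  s2 <- simulate_lfq_screen(p, "screen2", noise_seed = 202)
  expect_identical(s1$truth$enriched_ids, s2$truth$enriched_ids)
  expect_false(identical(s1$table, s2$table))
  r1 <- run_enrichment_screen(s1$table, enrichment_config(seed = 1))
  r2 <- run_enrichment_screen(s2$table, enrichment_config(seed = 2))
  truth <- s1$truth$enriched_ids
  prec <- function(ids) if (length(ids)) mean(ids %in% truth) else 1
  both <- intersect_screens(r1, r2)$intersection
  expect_gte(prec(both), prec(r1$protein_id[r1$significant]))
  expect_gte(prec(both), prec(r2$protein_id[r2$significant]))
})
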