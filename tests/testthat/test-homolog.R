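test_that("the BLAST tabular parser types fields and reports bad lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("q1", "s1", "35.2", "270", "150", "8", "1", "270",
                   "300", "565", "3e-50", "180", sep = "\t"), f)
  h <- parse_blast_tab(f)
  expect_equal(nrow(h), 1)
  expect_equal(h$evalue, 3e-50)
  expect_equal(h$pident, 35.2)
  expect_type(h$length, "integer")
  # wrong column count names the offending line
  writeLines(c(paste(rep("x", 12), collapse = "\t"),
               paste(rep("x", 11), collapse = "\t")), f)
  expect_error(parse_blast_tab(f), "line 2")
})

test_that("homolog calling applies the inclusive E-value cutoff with union dedup", {
  cfg <- survey_config()
  mk <- function(q, s, e) {
    h <- random_blast_hits(length(q), seed = 1)
    h$qseqid <- q
    h$sseqid <- s
    h$evalue <- e
    h
  }
  hits <- mk(q = c("btuH1", "btuH2", "btuG1", "btuH1", "btuH2"),
             s = c("gA|p1", "gA|p1", "gA|p2", "gB|p3", "gB|p4"),
             e = c(1e-50, 1e-40, 0.03, 0.031, 2))
  calls <- call_homologs(hits, cfg)
  # boundary: exactly 0.03 is called, 0.031 is not
  expect_setequal(calls$protein_id, c("p1", "p2"))
  # one call per subject, best E-value across queries, sources recorded
  p1 <- calls[calls$protein_id == "p1", ]
  expect_equal(nrow(p1), 1)
  expect_equal(p1$best_evalue, 1e-50)
  expect_equal(p1$source_queries, "btuH1,btuH2")
  expect_equal(p1$genome_id, "gA")
  # idempotence and cutoff monotonicity
  expect_identical(call_homologs(hits, cfg), calls)
  looser <- survey_config(homolog_evalue_cutoff = 1)
  expect_true(all(calls$sseqid %in% call_homologs(hits, looser)$sseqid))
  # non-homolog queries are ignored
  hits2 <- rbind(hits, mk("otherquery", "gC|p9", 1e-80))
  expect_false("p9" %in% call_homologs(hits2, cfg)$protein_id)
  # explicit subject->genome map overrides the id convention
  mapped <- call_homologs(
    mk("btuH1", "plainsubject", 1e-9), cfg,
    subject_genomes = data.frame(protein_id = "plainsubject",
                                 genome_id = "gZ"))
  expect_equal(mapped$genome_id, "gZ")
})

test_that("domain architecture assignment follows the 1e-3 rule", {
  cfg <- survey_config()
  calls <- call_homologs({
    h <- random_blast_hits(3, seed = 2)
    h$qseqid <- "btuH1"
    h$sseqid <- c("g1|a", "g1|b", "g2|c")
    h$evalue <- 1e-20
    h
  }, cfg)
  dmn <- random_blast_hits(5, seed = 3)
  dmn$qseqid <- c("btuG2", "btuH2_pkd1", "btuH2_pkd2", "btuG2", "btuH2_pkd1")
  dmn$sseqid <- c("g1|a", "g1|b", "g1|b", "g2|c", "g2|c")
  dmn$evalue <- c(1e-10, 1e-5, 1e-4, 1e-2, 1e-2)
  out <- assign_domains(calls, dmn, cfg)
  expect_equal(out$architecture[out$protein_id == "a"], "beta_propeller")
  # both PKD regions qualify: pkd with two counted hits
  expect_equal(out$architecture[out$protein_id == "b"], "pkd")
  expect_equal(out$pkd_hit_count[out$protein_id == "b"], 2L)
  # hits above 1e-3 leave the architecture at none
  expect_equal(out$architecture[out$protein_id == "c"], "none")
  expect_equal(out$pkd_hit_count[out$protein_id == "c"], 0L)
  # both domain types qualifying: classified by the lower E-value,
  # both recorded
  tie <- dmn[1:2, ]
  tie$sseqid <- "g1|a"
  tie$evalue <- c(1e-4, 1e-9)  # beta_propeller 1e-4, PKD1 1e-9
  out2 <- assign_domains(calls, tie, cfg)
  expect_equal(out2$architecture[out2$protein_id == "a"], "pkd")
  expect_true(out2$has_beta_propeller[out2$protein_id == "a"])
  # unknown domain query is a configuration error
  bad <- dmn
  bad$qseqid[1] <- "mystery"
  expect_error(assign_domains(calls, bad, cfg), "mystery")
  expect_error(survey_config(domain_queries = c(q = "sh3")), "unknown")
})

test_that("operon classification is exhaustive, exclusive and conserving", {
  operons <- data.frame(
    operon_id = c("op1", "op1", "op2", "op2", "op3", "op4"),
    genome_id = "g1",
    gene_id = c("h1", "b1", "h2", "x1", "b2", "y1"),
    stringsAsFactors = FALSE)
  calls <- data.frame(genome_id = "g1", protein_id = c("h1", "h2"),
                      stringsAsFactors = FALSE)
  btub <- data.frame(genome_id = "g1", gene_id = c("b1", "b2"),
                     stringsAsFactors = FALSE)
  cl <- classify_operons(operons, calls, btub)
  expect_equal(cl$classes$class[cl$classes$operon_id == "op1"], "both")
  expect_equal(cl$classes$class[cl$classes$operon_id == "op2"], "btuh_only")
  expect_equal(cl$classes$class[cl$classes$operon_id == "op3"], "btub_only")
  # op4 has neither and is excluded; counts sum to the relevant operons
  expect_false("op4" %in% cl$classes$operon_id)
  expect_equal(unname(cl$counts), c(1L, 1L, 1L))
  expect_equal(sum(cl$counts), nrow(cl$classes))
  # each call is tallied in at most one operon class
  expect_equal(nrow(cl$call_operon), 2)
  expect_false(any(duplicated(cl$call_operon$protein_id)))
  # unknown genome reference is a data error
  expect_error(
    classify_operons(operons, calls, btub,
                     genomes = data.frame(genome_id = "g2")),
    "unknown genome")
  # a gene in two operons of one genome violates the membership invariant
  dup <- rbind(operons, data.frame(operon_id = "op9", genome_id = "g1",
                                   gene_id = "h1"))
  expect_error(classify_operons(dup, calls, btub), "more than one operon")
})

test_that("panel summaries compute the prevalence fractions", {
  genomes <- data.frame(genome_id = c("g1", "g2", "g3"),
                        stringsAsFactors = FALSE)
  calls <- data.frame(genome_id = c("g1", "g1", "g2"),
                      protein_id = c("h1", "h2", "h3"),
                      architecture = c("pkd", "none", "none"),
                      stringsAsFactors = FALSE)
  s <- summarize_panel(genomes, calls)
  expect_equal(s$frac_genomes_with_btuh, 2 / 3)
  expect_equal(unname(s$paralog_count), c(2L, 1L, 0L))
  # zero calls: all fractions zero
  s0 <- summarize_panel(genomes, calls[0, ])
  expect_equal(s0$frac_genomes_with_btuh, 0)
  expect_equal(sum(s0$paralog_count), 0L)
  # calls referencing unknown genomes are a data error
  expect_error(summarize_panel(genomes[c(1, 3), , drop = FALSE], calls),
               "unknown genome")
})

test_that("a planted co-operonic fraction is recovered from the survey", {
  p <- panel_sim_params(n_genomes = 400, frac_co_operonic = 0.8, seed = 77)
  panel <- simulate_genome_panel(p)
  calls <- call_homologs(panel$hits)
  s <- summarize_panel(panel$genomes, calls, panel$operons, panel$btub)
  n_calls <- nrow(calls)
  expect_gt(n_calls, 300)  # enough homologs for a tight interval
  # recovered fraction within the binomial 99% interval around 0.8
  half <- qnorm(0.995) * sqrt(0.8 * 0.2 / n_calls)
  expect_gt(s$frac_homologs_co_operonic_with_btub, 0.8 - half)
  expect_lt(s$frac_homologs_co_operonic_with_btub, 0.8 + half)
  # class counts cover every surveyed operon exactly once
  cl <- classify_operons(panel$operons, calls, panel$btub, panel$genomes)
  expect_equal(sum(cl$counts), nrow(cl$classes))
})
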