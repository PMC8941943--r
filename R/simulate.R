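#' Parameters for a simulated LFQ enrichment screen
#'
#' Defines the generative model for a synthetic affinity-probe screen with a
#' known enriched set. Per-protein log2 baseline abundances are
#' Normal(`baseline_mean`, `baseline_sd`); each replicate adds
#' Normal(0, `rep_sd`) noise; proteins in the planted enriched set get an
#' additive `effect_log2` shift in the probe group only. Each cell is then
#' independently censored (set to 0 = missing) with probability
#' `plogis((missing_midpoint - log2 intensity) / missing_scale)`, a
#' left-censoring (missing-not-at-random) mechanism: the lower the
#' abundance, the likelier the dropout. A fraction of non-enriched proteins
#' are emitted as contaminant-flagged or low-peptide decoys that the
#' downstream filters are expected to remove.
#'
#' The defaults mirror a two-condition screen in biological quadruplicate
#' with strong planted effects (50/1000 proteins shifted +3 log2 units,
#' replicate SD 0.5); set `missing_midpoint = -Inf` for a fully observed
#' table.
#'
#' @param n_proteins Number of protein groups.
#' @param n_enriched Number of planted probe-enriched proteins (chosen among
#'   non-decoy proteins).
#' @param effect_log2 Additive log2 shift in the probe group for enriched
#'   proteins.
#' @param baseline_mean,baseline_sd Population mean / SD of per-protein log2
#'   baseline abundance.
#' @param rep_sd Replicate-to-replicate SD in log2 units.
#' @param n_replicates Replicates per group (probe and control alike).
#' @param missing_midpoint,missing_scale Logistic dropout parameters on the
#'   log2 scale; `missing_scale` must be positive so the dropout probability
#'   is non-increasing in abundance.
#' @param frac_contaminant Fraction of proteins flagged as contaminants.
#' @param frac_low_peptide Fraction of proteins with peptide count < 3.
#' @param seed RNG seed; identical parameters and seed reproduce the screen
#'   exactly.
#' @return A list of class `"lfq_sim_params"`.
#' @seealso [simulate_lfq_screen()]
#' @export
lfq_sim_params <- function(n_proteins = 1000, n_enriched = 50,
                           effect_log2 = 3, baseline_mean = 25,
                           baseline_sd = 2, rep_sd = 0.5,
                           n_replicates = 4, missing_midpoint = 22,
                           missing_scale = 1, frac_contaminant = 0.05,
                           frac_low_peptide = 0.10, seed = 1) {
  stop_if_not_scalar_number(n_proteins, "n_proteins", lo = 1)
  stop_if_not_scalar_number(n_enriched, "n_enriched", lo = 0)
  stop_if_not_scalar_number(effect_log2, "effect_log2")
  stop_if_not_scalar_number(baseline_mean, "baseline_mean")
  stop_if_not_scalar_number(baseline_sd, "baseline_sd", lo = 0)
  stop_if_not_scalar_number(rep_sd, "rep_sd", lo = 0)
  stop_if_not_scalar_number(n_replicates, "n_replicates", lo = 2)
  stop_if_not_scalar_number(missing_midpoint, "missing_midpoint",
                            allow_inf = TRUE)
  stop_if_not_scalar_number(missing_scale, "missing_scale")
  if (missing_scale <= 0) stop("'missing_scale' must be positive")
  stop_if_not_scalar_number(frac_contaminant, "frac_contaminant", 0, 1)
  stop_if_not_scalar_number(frac_low_peptide, "frac_low_peptide", 0, 1)
  stop_if_not_scalar_number(seed, "seed")
  if (n_enriched > n_proteins) stop("n_enriched must be <= n_proteins")
  structure(list(
    n_proteins = as.integer(n_proteins), n_enriched = as.integer(n_enriched),
    effect_log2 = effect_log2, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, rep_sd = rep_sd,
    n_replicates = as.integer(n_replicates),
    missing_midpoint = missing_midpoint, missing_scale = missing_scale,
    frac_contaminant = frac_contaminant, frac_low_peptide = frac_low_peptide,
    seed = as.integer(seed)
  ), class = "lfq_sim_params")
}

#' Simulate an LFQ enrichment screen with planted truth
#'
#' Draws a [protein_quant_table()] under the model described in
#' [lfq_sim_params()] and returns it together with the planted ground truth
#' (which protein ids were enriched and by how much), so recovery, false
#' discovery proportion and calibration can be measured downstream.
#'
#' @param params An [lfq_sim_params()] object.
#' @param screen_id Label attached to the generated table.
#' @param noise_seed Optional separate seed for the replicate-noise and
#'   dropout draws. The screen's structure (which proteins are decoys,
#'   which are enriched, the baseline abundances) always comes from
#'   `params$seed`, so two calls with the same `params` but different
#'   `noise_seed` yield independent screens sharing the same planted truth
#'   -- the design of paired independent screens.
#' @return List with elements `table` (a `protein_quant` data.frame) and
#'   `truth` (list: `enriched_ids`, `effect_log2`).
#' @examples
#' sim <- simulate_lfq_screen(lfq_sim_params(n_proteins = 200, seed = 7))
#' nrow(sim$table)
#' length(sim$truth$enriched_ids)
#' @export
simulate_lfq_screen <- function(params, screen_id = "screen1",
                                noise_seed = NULL) {
  stopifnot(inherits(params, "lfq_sim_params"))
  p <- params
  n <- p$n_proteins
  k <- p$n_replicates
  design <- with_seed(p$seed, {
    ids <- sprintf("P%05d", seq_len(n))
    n_cont <- round(p$frac_contaminant * n)
    n_lowp <- round(p$frac_low_peptide * n)
    shuffled <- sample.int(n)
    cont_idx <- shuffled[seq_len(n_cont)]
    lowp_idx <- shuffled[n_cont + seq_len(n_lowp)]
    clean <- setdiff(seq_len(n), c(cont_idx, lowp_idx))
    if (p$n_enriched > length(clean)) {
      stop("n_enriched exceeds the number of non-decoy proteins")
    }
    enriched <- sort(sample(clean, p$n_enriched))
    peptide <- sample(3:30, n, replace = TRUE)
    peptide[lowp_idx] <- sample(1:2, length(lowp_idx), replace = TRUE)
    contaminant <- rep(FALSE, n)
    contaminant[cont_idx] <- TRUE
    base <- stats::rnorm(n, p$baseline_mean, p$baseline_sd)
    list(ids = ids, enriched = enriched, peptide = peptide,
         contaminant = contaminant, base = base)
  })
  samples <- c(paste0("probe_", seq_len(k)), paste0("control_", seq_len(k)))
  groups <- stats::setNames(rep(c("probe", "control"), each = k), samples)
  intensity <- with_seed(noise_seed %||% (p$seed + 1L), {
    logm <- matrix(design$base, n, 2 * k) +
      matrix(stats::rnorm(n * 2 * k, 0, p$rep_sd), n, 2 * k)
    logm[design$enriched, seq_len(k)] <-
      logm[design$enriched, seq_len(k)] + p$effect_log2
    p_miss <- stats::plogis((p$missing_midpoint - logm) / p$missing_scale)
    miss <- matrix(stats::runif(n * 2 * k) < p_miss, n, 2 * k)
    out <- 2^logm
    out[miss] <- 0
    out
  })
  proteins <- data.frame(protein_id = design$ids,
                         peptide_count = design$peptide,
                         contaminant = design$contaminant,
                         stringsAsFactors = FALSE)
  for (j in seq_along(samples)) proteins[[samples[j]]] <- intensity[, j]
  list(
    table = protein_quant_table(proteins, groups, screen_id),
    truth = list(enriched_ids = design$ids[design$enriched],
                 effect_log2 = p$effect_log2)
  )
}

#' Parameters for a simulated genome panel
#'
#' Defines a panel of genomes carrying an ordered cobamide-biosynthesis
#' category (by convention ordered by increasing dependence on transport,
#' e.g. early-precursor salvage < late-precursor salvage < transport only)
#' and a per-genome count of btuH-like homologs drawn as
#' Poisson(`lambda_by_category[category]`). Each homolog is placed in an
#' operon; with probability `frac_co_operonic` that operon also contains a
#' btuB member, so the co-operonic fraction of the panel is recoverable.
#'
#' @param n_genomes Number of genomes in the panel.
#' @param category_props Named proportions over the ordered categories
#'   (must sum to 1; names give the category order, least to most
#'   transport-dependent).
#' @param lambda_by_category Expected homolog copy number per category, same
#'   length/order as `category_props`.
#' @param frac_co_operonic Probability that a homolog's operon also carries
#'   btuB.
#' @param seed RNG seed.
#' @return A list of class `"panel_sim_params"`.
#' @seealso [simulate_genome_panel()]
#' @export
panel_sim_params <- function(n_genomes = 500,
                             category_props = c(salvage_early = 0.30,
                                                salvage_late = 0.30,
                                                transport_only = 0.40),
                             lambda_by_category = c(0.3, 1.0, 2.0),
                             frac_co_operonic = 0.8, seed = 1) {
  stop_if_not_scalar_number(n_genomes, "n_genomes", lo = 1)
  if (length(category_props) < 1 || is.null(names(category_props))) {
    stop("category_props must be a non-empty named vector")
  }
  if (any(category_props < 0) || abs(sum(category_props) - 1) > 1e-8) {
    stop("category_props must be non-negative and sum to 1")
  }
  if (length(lambda_by_category) != length(category_props)) {
    stop("lambda_by_category must match category_props in length")
  }
  if (any(!is.finite(lambda_by_category)) || any(lambda_by_category < 0)) {
    stop("lambda values must be finite and >= 0")
  }
  stop_if_not_scalar_number(frac_co_operonic, "frac_co_operonic", 0, 1)
  stop_if_not_scalar_number(seed, "seed")
  structure(list(
    n_genomes = as.integer(n_genomes),
    category_props = category_props,
    lambda_by_category = stats::setNames(lambda_by_category,
                                         names(category_props)),
    frac_co_operonic = frac_co_operonic, seed = as.integer(seed)
  ), class = "panel_sim_params")
}

#' Simulate a genome panel with planted category/copy-number structure
#'
#' Generates the tables the homolog survey and association statistics
#' consume: genome metadata with ordered biosynthesis categories, a homolog
#' table (one row per btuH-like gene), operon membership, a btuB call table,
#' and a 12-column BLAST hit table in which every planted homolog is hit by
#' one of the three homolog queries below the E-value cutoff (decoy subjects
#' above the cutoff are included). Subject ids follow the
#' `"<genome>|<gene>"` convention so hits can be attributed to genomes.
#'
#' @param params A [panel_sim_params()] object.
#' @return List with elements `genomes`, `homologs`, `operons`, `btub`,
#'   `hits` (data.frames) and `truth` (list: `panel_lambda`,
#'   `category_order`, `frac_co_operonic`).
#' @examples
#' panel <- simulate_genome_panel(panel_sim_params(n_genomes = 50, seed = 3))
#' head(panel$genomes)
#' @export
simulate_genome_panel <- function(params) {
  stopifnot(inherits(params, "panel_sim_params"))
  p <- params
  cats <- names(p$category_props)
  with_seed(p$seed, {
    n <- p$n_genomes
    gids <- sprintf("G%04d", seq_len(n))
    category <- sample(cats, n, replace = TRUE, prob = p$category_props)
    copies <- stats::rpois(n, p$lambda_by_category[category])

    genomes <- data.frame(
      genome_id = gids, phylum = "Bacteroidetes", gut_flag = TRUE,
      biosynthesis_category = factor(category, levels = cats, ordered = TRUE),
      stringsAsFactors = FALSE
    )

    # every genome carries 1-3 btuB-containing operons; each homolog joins
    # one of them with prob frac_co_operonic, otherwise gets its own operon
    n_btub_ops <- 1L + stats::rpois(n, 0.5)
    operons <- list(); homologs <- list(); btub <- list()
    for (i in seq_len(n)) {
      g <- gids[i]
      bops <- sprintf("%s_op%02d", g, seq_len(n_btub_ops[i]))
      bgenes <- sprintf("%s_btuB_%d", g, seq_len(n_btub_ops[i]))
      operons[[length(operons) + 1L]] <-
        data.frame(operon_id = bops, genome_id = g, gene_id = bgenes,
                   stringsAsFactors = FALSE)
      btub[[length(btub) + 1L]] <-
        data.frame(genome_id = g, gene_id = bgenes, stringsAsFactors = FALSE)
      if (copies[i] > 0) {
        hgenes <- sprintf("%s_btuH_%d", g, seq_len(copies[i]))
        co <- stats::runif(copies[i]) < p$frac_co_operonic
        host <- character(copies[i])
        host[co] <- sample(bops, sum(co), replace = TRUE)
        if (any(!co)) {
          host[!co] <- sprintf("%s_solo%02d", g, seq_len(sum(!co)))
        }
        operons[[length(operons) + 1L]] <-
          data.frame(operon_id = host, genome_id = g, gene_id = hgenes,
                     stringsAsFactors = FALSE)
        homologs[[length(homologs) + 1L]] <-
          data.frame(genome_id = g, protein_id = hgenes,
                     stringsAsFactors = FALSE)
      }
    }
    homologs <- if (length(homologs)) do.call(rbind, homologs) else
      data.frame(genome_id = character(), protein_id = character(),
                 stringsAsFactors = FALSE)
    operons <- do.call(rbind, operons)
    btub <- do.call(rbind, btub)
    rownames(homologs) <- rownames(operons) <- rownames(btub) <- NULL

    hits <- panel_blast_hits(homologs, genome_ids = gids,
                             n_decoys = max(1L, round(0.2 * n)))

    list(genomes = genomes, homologs = homologs, operons = operons,
         btub = btub, hits = hits,
         truth = list(panel_lambda = p$lambda_by_category,
                      category_order = cats,
                      frac_co_operonic = p$frac_co_operonic))
  })
}

# BLAST outfmt 6 hits for the planted homologs (E <= 0.03 guaranteed) plus
# decoy subjects above the cutoff. Uses the ambient RNG stream.
panel_blast_hits <- function(homologs, genome_ids, n_decoys = 50L,
                             queries = c("btuH1", "btuG1", "btuH2")) {
  subj <- character(0)
  gen <- character(0)
  ev <- numeric(0)
  qq <- character(0)
  if (nrow(homologs)) {
    n_hits_each <- 1L + stats::rpois(nrow(homologs), 0.5)
    idx <- rep(seq_len(nrow(homologs)), n_hits_each)
    subj <- homologs$protein_id[idx]
    gen <- homologs$genome_id[idx]
    qq <- sample(queries, length(idx), replace = TRUE)
    ev <- 10^(-stats::runif(length(idx), 2, 50))
  }
  if (n_decoys > 0) {
    dg <- sample(genome_ids, n_decoys, replace = TRUE)
    subj <- c(subj, sprintf("%s_decoy_%d", dg, seq_len(n_decoys)))
    gen <- c(gen, dg)
    qq <- c(qq, sample(queries, n_decoys, replace = TRUE))
    ev <- c(ev, stats::runif(n_decoys, 0.05, 10))
  }
  m <- length(subj)
  alen <- sample(80:400, m, replace = TRUE)
  data.frame(
    qseqid = qq,
    sseqid = paste0(gen, "|", subj),
    pident = round(stats::runif(m, 20, 95), 2),
    length = alen,
    mismatch = sample(0:150, m, replace = TRUE),
    gapopen = sample(0:10, m, replace = TRUE),
    qstart = 1L, qend = alen,
    sstart = 1L, send = alen,
    evalue = ev,
    bitscore = round(stats::runif(m, 30, 900), 1),
    stringsAsFactors = FALSE
  )
}

#' Write BLAST tabular (outfmt 6) hits
#'
#' Emits the standard 12-column tab-separated BLAST format. Numeric columns
#' are written with full double precision so that
#' `parse_blast_tab(write_blast_tab(h, f))` reproduces `h` exactly.
#'
#' @param hits data.frame with the 12 standard columns (see
#'   [parse_blast_tab()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  if (!all(blast_columns %in% names(hits))) {
    stop("hits must have the 12 standard BLAST tabular columns")
  }
  if (nrow(hits) == 0) {
    file.create(path)
    return(invisible(path))
  }
  fmt_num <- function(x) sprintf("%.17g", as.numeric(x))
  lines <- paste(hits$qseqid, hits$sseqid, fmt_num(hits$pident),
                 as.integer(hits$length), as.integer(hits$mismatch),
                 as.integer(hits$gapopen), as.integer(hits$qstart),
                 as.integer(hits$qend), as.integer(hits$sstart),
                 as.integer(hits$send), fmt_num(hits$evalue),
                 fmt_num(hits$bitscore), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write the tables of a simulated genome panel to a directory
#'
#' Emits `genomes.tsv`, `operons.tsv`, `btub.tsv`, `hits.tsv` (BLAST
#' outfmt 6) and `truth.json` for a panel from [simulate_genome_panel()].
#'
#' @param panel Result of [simulate_genome_panel()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_panel_tables <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(panel$genomes, "genomes.tsv")
  tsv(panel$operons, "operons.tsv")
  tsv(panel$btub, "btub.tsv")
  write_blast_tab(panel$hits, file.path(dir, "hits.tsv"))
  jsonlite::write_json(panel$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
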