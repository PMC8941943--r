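blast_columns <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Parse BLAST tabular (outfmt 6) hits
#'
#' Reads the standard 12-column tab-separated BLAST output into a typed
#' data.frame (scientific-notation E-values included). An empty file yields
#' a zero-row frame; a line with the wrong number of columns raises an
#' error naming that line.
#'
#' @param path Path to the tabular file.
#' @return data.frame with columns `qseqid`, `sseqid`, `pident`, `length`,
#'   `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#'   `bitscore`.
#' @seealso [write_blast_tab()]
#' @export
parse_blast_tab <- function(path) {
  empty <- data.frame(qseqid = character(), sseqid = character(),
                      pident = numeric(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  nf <- utils::count.fields(path, sep = "\t", quote = "",
                            comment.char = "")
  bad <- which(nf != 12L)
  if (length(bad)) {
    stop(sprintf("line %d of '%s' has %d columns (expected 12)",
                 bad[1], path, nf[bad[1]]))
  }
  hits <- utils::read.delim(
    path, header = FALSE, quote = "", comment.char = "",
    col.names = blast_columns, stringsAsFactors = FALSE,
    colClasses = c("character", "character", "numeric", "integer",
                   "integer", "integer", "integer", "integer", "integer",
                   "integer", "numeric", "numeric"))
  if (any(hits$evalue < 0)) stop("negative E-value in '", path, "'")
  hits
}

#' Configuration for the homolog survey
#'
#' Holds the E-value cutoffs and query labels of the comparative survey.
#' Homolog calls use an inclusive cutoff (E <= `homolog_evalue_cutoff`,
#' default 0.03) over the union of the three homolog queries; N-terminal
#' domain assignment uses E <= `domain_evalue_cutoff` (default 1e-3).
#' `domain_queries` maps each domain query id to its domain label:
#' `"beta_propeller"` for the BtuG-style query, `"PKD1"` / `"PKD2"` for the
#' two PKD-region queries (coding-sequence sub-ranges bp 91-294 and
#' bp 364-540 of the btuH2 query, 1-based inclusive).
#'
#' @param homolog_evalue_cutoff Inclusive E-value cutoff for homolog calls.
#' @param domain_evalue_cutoff Inclusive E-value cutoff for domain hits.
#' @param homolog_queries Query ids whose hits are pooled for calling.
#' @param domain_queries Named character vector: query id -> domain label in
#'   `{beta_propeller, PKD1, PKD2}`.
#' @return A list of class `"survey_config"`.
#' @export
survey_config <- function(homolog_evalue_cutoff = 0.03,
                          domain_evalue_cutoff = 1e-3,
                          homolog_queries = c("btuH1", "btuG1", "btuH2"),
                          domain_queries = c(btuG2 = "beta_propeller",
                                             btuH2_pkd1 = "PKD1",
                                             btuH2_pkd2 = "PKD2")) {
  stop_if_not_scalar_number(homolog_evalue_cutoff, "homolog_evalue_cutoff")
  stop_if_not_scalar_number(domain_evalue_cutoff, "domain_evalue_cutoff")
  if (homolog_evalue_cutoff <= 0 || domain_evalue_cutoff <= 0) {
    stop("E-value cutoffs must be positive")
  }
  allowed <- c("beta_propeller", "PKD1", "PKD2")
  if (!all(domain_queries %in% allowed)) {
    stop("unknown domain label(s): ",
         paste(setdiff(domain_queries, allowed), collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  structure(list(homolog_evalue_cutoff = homolog_evalue_cutoff,
                 domain_evalue_cutoff = domain_evalue_cutoff,
                 homolog_queries = homolog_queries,
                 domain_queries = domain_queries),
            class = "survey_config")
}

# Split "<genome>|<protein>" subject ids; map overrides the convention.
subject_genome <- function(sseqid, subject_genomes = NULL) {
  if (!is.null(subject_genomes)) {
    g <- subject_genomes$genome_id[match(sseqid,
                                         subject_genomes$protein_id)]
    if (any(is.na(g))) {
      stop("subject(s) missing from subject_genomes map: ",
           paste(utils::head(sseqid[is.na(g)], 3), collapse = ", "))
    }
    return(list(genome_id = g, protein_id = sseqid))
  }
  has_pipe <- grepl("|", sseqid, fixed = TRUE)
  if (!all(has_pipe)) {
    stop("subject ids lack the '<genome>|<protein>' convention and no ",
         "subject_genomes map was given")
  }
  list(genome_id = sub("\\|.*$", "", sseqid),
       protein_id = sub("^[^|]*\\|", "", sseqid))
}

#' Call homologs from pooled similarity-search hits
#'
#' Designates as homologs all subjects hit by at least one of the homolog
#' queries with E-value at or below the cutoff (inclusive, matching the
#' published "E <= 0.03" rule). A subject hit by several queries yields a
#' single call whose `best_evalue` is the minimum over its qualifying hits
#' and whose `source_queries` lists every query that hit it below the
#' cutoff.
#'
#' @param hits BLAST hit data.frame (see [parse_blast_tab()]); hits from
#'   all homolog queries pooled.
#' @param config A [survey_config()].
#' @param subject_genomes Optional data.frame (`protein_id`, `genome_id`)
#'   attributing subjects to genomes; by default subject ids are split on
#'   the first `"|"` as `"<genome>|<protein>"`.
#' @return data.frame of class `"homolog_calls"`: `genome_id`,
#'   `protein_id`, `sseqid`, `best_evalue`, `source_queries`,
#'   `architecture` (initially `"none"`), `pkd_hit_count`.
#' @export
call_homologs <- function(hits, config = survey_config(),
                          subject_genomes = NULL) {
  keep <- hits$qseqid %in% config$homolog_queries &
    hits$evalue <= config$homolog_evalue_cutoff
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0) {
    out <- data.frame(genome_id = character(), protein_id = character(),
                      sseqid = character(), best_evalue = numeric(),
                      source_queries = character(),
                      architecture = character(), pkd_hit_count = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("homolog_calls", "data.frame")
    return(out)
  }
  best <- tapply(h$evalue, h$sseqid, min)
  srcs <- tapply(h$qseqid, h$sseqid,
                 function(q) paste(sort(unique(q)), collapse = ","))
  subj <- names(best)
  ids <- subject_genome(subj, subject_genomes)
  out <- data.frame(genome_id = ids$genome_id, protein_id = ids$protein_id,
                    sseqid = subj, best_evalue = as.numeric(best),
                    source_queries = as.character(srcs),
                    architecture = "none", pkd_hit_count = 0L,
                    stringsAsFactors = FALSE)
  out <- out[order(out$genome_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("homolog_calls", "data.frame")
  out
}

#' Assign N-terminal domain architectures to homolog calls
#'
#' Labels each call from the domain-query hits at the inclusive domain
#' cutoff (default 1e-3): `beta_propeller` if the BtuG-style query
#' qualifies, `pkd` if either PKD-region query qualifies
#' (`pkd_hit_count` = number of qualifying PKD-region hits), `none`
#' otherwise. If both domain types qualify for one subject, the call is
#' classified by the lower E-value and both are recorded in the
#' `has_beta_propeller` / `has_pkd` columns.
#'
#' @param calls Result of [call_homologs()].
#' @param domain_hits BLAST hit data.frame whose `qseqid` values appear in
#'   `names(config$domain_queries)`; subjects are matched on `sseqid`.
#' @param config A [survey_config()].
#' @return `calls` with updated `architecture`, `pkd_hit_count` and added
#'   `has_beta_propeller`, `has_pkd` columns.
#' @export
assign_domains <- function(calls, domain_hits, config = survey_config()) {
  unknown <- setdiff(unique(domain_hits$qseqid),
                     names(config$domain_queries))
  if (length(unknown)) {
    stop("domain hits from unconfigured quer",
         if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "))
  }
  lab <- unname(config$domain_queries[domain_hits$qseqid])
  qual <- domain_hits$evalue <= config$domain_evalue_cutoff
  best_by_subject <- function(sel) {
    if (!any(sel)) return(stats::setNames(numeric(0), character(0)))
    tapply(domain_hits$evalue[sel], domain_hits$sseqid[sel], min)
  }
  bp_best <- best_by_subject(qual & lab == "beta_propeller")
  pkd_sel <- qual & lab %in% c("PKD1", "PKD2")
  pkd_best <- best_by_subject(pkd_sel)
  pkd_n <- table(domain_hits$sseqid[pkd_sel])

  bp_e <- as.numeric(bp_best[calls$sseqid])
  pkd_e <- as.numeric(pkd_best[calls$sseqid])
  has_bp <- !is.na(bp_e)
  has_pkd <- !is.na(pkd_e)
  arch <- rep("none", nrow(calls))
  arch[has_bp & !has_pkd] <- "beta_propeller"
  arch[has_pkd & !has_bp] <- "pkd"
  tie <- has_bp & has_pkd
  arch[tie] <- ifelse(bp_e[tie] <= pkd_e[tie], "beta_propeller", "pkd")
  calls$architecture <- arch
  cnt <- as.integer(pkd_n[calls$sseqid])
  calls$pkd_hit_count <- ifelse(is.na(cnt), 0L, cnt)
  calls$has_beta_propeller <- has_bp
  calls$has_pkd <- has_pkd
  calls
}

#' Classify operons by homolog content
#'
#' Each operon containing at least one called btuH-like homolog or at least
#' one btuB member is placed in exactly one class: `both`, `btuh_only` or
#' `btub_only`; operons with neither are excluded from the counts. btuB
#' calls are supplied as an input table (they come from prior annotation,
#' not from this survey).
#'
#' @param operons Long-format data.frame: `operon_id`, `genome_id`,
#'   `gene_id` (one row per member gene; a gene may appear in at most one
#'   operon per genome).
#' @param homolog_calls Result of [call_homologs()].
#' @param btub_calls data.frame with `genome_id`, `gene_id` of btuB members.
#' @param genomes Optional genome-metadata data.frame with `genome_id`;
#'   when given, an operon referencing an unknown genome is an error.
#' @return List with `classes` (data.frame `operon_id`, `genome_id`,
#'   `class` for the counted operons), `counts` (named vector `btuh_only`,
#'   `btub_only`, `both`) and `call_operon` (data.frame mapping each call
#'   assigned to a surveyed operon to its operon and class).
#' @export
classify_operons <- function(operons, homolog_calls, btub_calls,
                             genomes = NULL) {
  if (!all(c("operon_id", "genome_id", "gene_id") %in% names(operons))) {
    stop("operons needs columns operon_id, genome_id, gene_id")
  }
  if (!is.null(genomes)) {
    bad <- setdiff(unique(operons$genome_id), genomes$genome_id)
    if (length(bad)) {
      stop("operon(s) reference unknown genome(s): ",
           paste(utils::head(bad, 3), collapse = ", "))
    }
  }
  dup <- duplicated(operons[, c("genome_id", "gene_id")])
  if (any(dup)) {
    stop("gene(s) assigned to more than one operon within a genome: ",
         paste(utils::head(operons$gene_id[dup], 3), collapse = ", "))
  }
  key <- function(g, x) paste(g, x, sep = "\r")
  h_keys <- key(homolog_calls$genome_id, homolog_calls$protein_id)
  b_keys <- key(btub_calls$genome_id, btub_calls$gene_id)
  member_key <- key(operons$genome_id, operons$gene_id)
  is_h <- member_key %in% h_keys
  is_b <- member_key %in% b_keys
  op_key <- key(operons$genome_id, operons$operon_id)
  has_h <- tapply(is_h, op_key, any)
  has_b <- tapply(is_b, op_key, any)
  ops <- !duplicated(op_key)
  op_tab <- data.frame(operon_id = operons$operon_id[ops],
                       genome_id = operons$genome_id[ops],
                       stringsAsFactors = FALSE)
  kk <- key(op_tab$genome_id, op_tab$operon_id)
  op_tab$class <- ifelse(has_h[kk] & has_b[kk], "both",
                         ifelse(has_h[kk], "btuh_only",
                                ifelse(has_b[kk], "btub_only", "none")))
  classes <- op_tab[op_tab$class != "none", , drop = FALSE]
  rownames(classes) <- NULL
  counts <- c(btuh_only = sum(classes$class == "btuh_only"),
              btub_only = sum(classes$class == "btub_only"),
              both = sum(classes$class == "both"))
  # map each call to its (unique within genome) operon and class
  midx <- match(h_keys, member_key)
  call_operon <- data.frame(
    genome_id = homolog_calls$genome_id,
    protein_id = homolog_calls$protein_id,
    operon_id = operons$operon_id[midx],
    stringsAsFactors = FALSE)
  call_operon <- call_operon[!is.na(call_operon$operon_id), , drop = FALSE]
  ck <- key(call_operon$genome_id, call_operon$operon_id)
  call_operon$class <- classes$class[match(ck, key(classes$genome_id,
                                                   classes$operon_id))]
  rownames(call_operon) <- NULL
  list(classes = classes, counts = counts, call_operon = call_operon)
}

#' Summarize a surveyed genome panel
#'
#' Computes the prevalence summary of a panel: the fraction of genomes with
#' at least one called homolog, per-genome paralog counts, the operon class
#' counts and the fraction of homologs that are co-operonic with btuB
#' (calls whose operon class is `both`, over calls assigned to any surveyed
#' operon).
#'
#' @param genomes Genome-metadata data.frame with `genome_id`.
#' @param calls Result of [call_homologs()] (optionally after
#'   [assign_domains()]).
#' @param operons,btub_calls As in [classify_operons()]; may be `NULL` to
#'   skip operon-level summaries.
#' @return A list of class `"panel_summary"`: `n_genomes`,
#'   `frac_genomes_with_btuh`, `operon_class_counts`,
#'   `frac_homologs_co_operonic_with_btub`, `paralog_count` (named integer
#'   vector over all genomes, zeros included), `architecture_counts`.
#' @export
summarize_panel <- function(genomes, calls, operons = NULL,
                            btub_calls = NULL) {
  gid <- genomes$genome_id
  paralog <- stats::setNames(integer(length(gid)), gid)
  if (nrow(calls)) {
    unknown <- setdiff(unique(calls$genome_id), gid)
    if (length(unknown)) {
      stop("call(s) reference unknown genome(s): ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
    tab <- table(calls$genome_id)
    paralog[names(tab)] <- as.integer(tab)
  }
  out <- list(
    n_genomes = length(gid),
    frac_genomes_with_btuh = mean(paralog >= 1),
    operon_class_counts = NULL,
    frac_homologs_co_operonic_with_btub = NA_real_,
    paralog_count = paralog,
    architecture_counts = if (nrow(calls)) table(calls$architecture) else
      table(character(0))
  )
  if (!is.null(operons) && !is.null(btub_calls)) {
    cl <- classify_operons(operons, calls, btub_calls, genomes)
    out$operon_class_counts <- cl$counts
    n_assigned <- nrow(cl$call_operon)
    out$frac_homologs_co_operonic_with_btub <-
      if (n_assigned > 0) mean(cl$call_operon$class == "both") else 0
  }
  class(out) <- "panel_summary"
  out
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("Genome panel survey: %d genomes\n", x$n_genomes))
  cat(sprintf("  genomes with >= 1 homolog : %.1f%%\n",
              100 * x$frac_genomes_with_btuh))
  if (!is.null(x$operon_class_counts)) {
    cat("  operon classes            : ",
        paste(names(x$operon_class_counts), x$operon_class_counts,
              sep = "=", collapse = ", "), "\n", sep = "")
    cat(sprintf("  homologs co-operonic with btuB: %.1f%%\n",
                100 * x$frac_homologs_co_operonic_with_btub))
  }
  invisible(x)
}
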