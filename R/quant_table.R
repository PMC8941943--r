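#' Construct a protein quantification table
#'
#' The in-memory container for a label-free quantification (LFQ) screen:
#' one row per protein group, with a unique id, the number of identifying
#' peptides, a contaminant flag, and one linear-scale intensity column per
#' sample. An intensity of 0 encodes "not observed" (the MaxQuant LFQ
#' convention). Each sample belongs to exactly one comparison group
#' (`"probe"` or `"control"`), and each group must have at least two
#' replicates.
#'
#' @param proteins data.frame with columns `protein_id`, `peptide_count`,
#'   `contaminant`, plus one numeric column per sample named in
#'   `sample_groups`.
#' @param sample_groups Named character vector mapping sample name to group
#'   (`"probe"` or `"control"`).
#' @param screen_id Label for the screen (e.g. `"screen1"`).
#' @return A data.frame of class `"protein_quant"` carrying the group map in
#'   `attr(, "sample_groups")` and the label in `attr(, "screen_id")`.
#' @seealso [read_quant_table()], [write_quant_table()],
#'   [simulate_lfq_screen()]
#' @export
protein_quant_table <- function(proteins, sample_groups,
                                screen_id = "screen1") {
  required <- c("protein_id", "peptide_count", "contaminant")
  if (!all(required %in% names(proteins))) {
    stop("proteins must have columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(proteins$protein_id)) {
    stop("duplicate protein ids: ",
         paste(unique(proteins$protein_id[duplicated(proteins$protein_id)]),
               collapse = ", "))
  }
  if (is.null(names(sample_groups)) || any(names(sample_groups) == "")) {
    stop("sample_groups must be a named vector (sample -> group)")
  }
  if (!all(sample_groups %in% c("probe", "control"))) {
    stop("groups must be 'probe' or 'control'")
  }
  if (any(table(sample_groups) < 2)) {
    stop("each group needs at least 2 replicate samples")
  }
  missing_cols <- setdiff(names(sample_groups), names(proteins))
  if (length(missing_cols)) {
    stop("missing intensity column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (s in names(sample_groups)) {
    v <- proteins[[s]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop("intensities in '", s, "' must be finite and >= 0 (0 = missing)")
    }
  }
  out <- proteins[, c(required, names(sample_groups)), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_groups") <- sample_groups
  attr(out, "screen_id") <- screen_id
  class(out) <- c("protein_quant", "data.frame")
  out
}

sample_names <- function(table) names(attr(table, "sample_groups"))

#' @export
print.protein_quant <- function(x, ...) {
  sg <- attr(x, "sample_groups")
  cat(sprintf("Protein quantification table '%s': %d proteins, %d samples (%d probe, %d control)\n",
              attr(x, "screen_id"), nrow(x), length(sg),
              sum(sg == "probe"), sum(sg == "control")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read a proteinGroups-style quantification table
#'
#' Parses the tab-separated dialect produced by MaxQuant's proteinGroups.txt
#' (and by [write_quant_table()]): columns `Protein IDs`, `Peptides`,
#' `Potential contaminant` (`"+"` flags a contaminant) and one
#' `LFQ intensity <sample>` column per configured sample. Empty or zero
#' intensity cells are treated as missing (stored as 0).
#'
#' @param path Path to the TSV file.
#' @param sample_groups Named character vector mapping sample name to group
#'   (`"probe"`/`"control"`); every sample must have a matching
#'   `LFQ intensity` column.
#' @param screen_id Label for the screen.
#' @return A [protein_quant_table()].
#' @export
read_quant_table <- function(path, sample_groups, screen_id = "screen1") {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (col in c("Protein IDs", "Peptides", "Potential contaminant")) {
    if (!col %in% names(raw)) stop("missing required column '", col, "'")
  }
  proteins <- data.frame(
    protein_id = as.character(raw[["Protein IDs"]]),
    peptide_count = as.integer(raw[["Peptides"]]),
    contaminant = !is.na(raw[["Potential contaminant"]]) &
      raw[["Potential contaminant"]] == "+",
    stringsAsFactors = FALSE
  )
  for (s in names(sample_groups)) {
    col <- paste("LFQ intensity", s)
    if (!col %in% names(raw)) {
      stop("missing intensity column for sample '", s, "' ('", col, "')")
    }
    v <- suppressWarnings(as.numeric(raw[[col]]))
    v[is.na(v)] <- 0
    proteins[[s]] <- v
  }
  protein_quant_table(proteins, sample_groups, screen_id)
}

#' Write a quantification table in the proteinGroups dialect
#'
#' Inverse of [read_quant_table()]: emits `Protein IDs`, `Peptides`,
#' `Potential contaminant` (`"+"` or empty) and `LFQ intensity <sample>`
#' columns as tab-separated text. Intensities are written with full double
#' precision so that a write/read round trip is exact.
#'
#' @param table A [protein_quant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(table, path) {
  stopifnot(inherits(table, "protein_quant"))
  samples <- sample_names(table)
  out <- data.frame(
    check.names = FALSE, stringsAsFactors = FALSE,
    "Protein IDs" = table$protein_id,
    "Peptides" = table$peptide_count,
    "Potential contaminant" = ifelse(table$contaminant, "+", "")
  )
  for (s in samples) {
    out[[paste("LFQ intensity", s)]] <- sprintf("%.17g", table[[s]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group assignment table
#'
#' Two-column TSV with header `sample`, `group`; used by the command-line
#' interface to build the `sample_groups` mapping.
#'
#' @param path Path to the TSV file.
#' @return Named character vector (sample -> group).
#' @export
read_groups_config <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(g))) {
    stop("groups config needs columns 'sample' and 'group'")
  }
  stats::setNames(g$group, g$sample)
}
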