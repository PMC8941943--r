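# Shared in-code fixtures for the suite.

toy_groups <- function() {
  stats::setNames(rep(c("probe", "control"), each = 4),
                  c(paste0("probe_", 1:4), paste0("control_", 1:4)))
}

# Hand-built quantification table exercising every filter rule.
# Retained set after filtering (min 3 peptides, no contaminants,
# all-4-in-one-group presence): KEEP1, KEEP2, KEEP3.
toy_quant_table <- function() {
  rows <- list(
    #            id       pep cont  probe (4)                control (4)
    list("KEEP1",   5L, FALSE, 2^c(10, 11, 10, 10), 2^c(5, 5, 6, 5)),
    list("KEEP2",   3L, FALSE, 2^c(12, 12, 13, 12), c(0, 0, 0, 0)),
    list("LOWPEP",  2L, FALSE, 2^c(10, 10, 10, 10), 2^c(6, 6, 6, 6)),
    list("CONT",   10L, TRUE,  2^c(10, 10, 10, 10), 2^c(6, 6, 6, 6)),
    list("PARTIAL", 8L, FALSE, c(2^10, 2^10, 2^10, 0), c(2^6, 2^6, 2^6, 0)),
    list("KEEP3",   4L, FALSE, c(2^9, 2^9, 0, 0),   2^c(7, 7, 7, 7))
  )
  proteins <- data.frame(
    protein_id = vapply(rows, `[[`, character(1), 1),
    peptide_count = vapply(rows, `[[`, integer(1), 2),
    contaminant = vapply(rows, `[[`, logical(1), 3),
    stringsAsFactors = FALSE
  )
  probe <- t(vapply(rows, `[[`, numeric(4), 4))
  ctrl <- t(vapply(rows, `[[`, numeric(4), 5))
  for (j in 1:4) proteins[[paste0("probe_", j)]] <- probe[, j]
  for (j in 1:4) proteins[[paste0("control_", j)]] <- ctrl[, j]
  protein_quant_table(proteins, toy_groups(), screen_id = "toy")
}

# The worked imputation matrix: global observed minimum 5, and after
# min-filling, mean(P1) = 57 / 8 = 7.125.
toy_log2_matrix <- function() {
  m <- rbind(P1 = c(10, 11, NA, 10, 5, 5, 6, NA),
             P2 = c(8, 8, 8, 8, 7, 7, 7, 7))
  colnames(m) <- names(toy_groups())
  m
}

random_blast_hits <- function(n, seed) {
  set.seed(seed)
  alen <- sample(50:500, n, replace = TRUE)
  data.frame(
    qseqid = sample(c("btuH1", "btuG1", "btuH2"), n, replace = TRUE),
    sseqid = sprintf("G%03d|prot_%03d", sample(1:40, n, TRUE), seq_len(n)),
    pident = round(runif(n, 15, 100), 2),
    length = alen,
    mismatch = sample(0:200, n, replace = TRUE),
    gapopen = sample(0:12, n, replace = TRUE),
    qstart = sample(1:50, n, replace = TRUE),
    qend = alen,
    sstart = sample(1:900, n, replace = TRUE),
    send = sample(1:900, n, replace = TRUE),
    evalue = 10^runif(n, -60, 1),
    bitscore = round(runif(n, 25, 1200), 1),
    stringsAsFactors = FALSE
  )
}

# O(m^2) reference implementation of the BH step-up adjustment.
bh_naive <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}
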