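# Per-gene fold changes, senescence-regulated gene-set classification,
# gene-length stratification, and Pol II pausing indices.

#' Per-gene log2 fold change of library-normalized counts
#'
#' `log2fc = log2(((count_b + pc) / libsize_b) / ((count_a + pc) /
#' libsize_a))`. The pseudocount guards zeros; with equal library sizes two
#' zero counts give exactly 0.
#'
#' @param counts_a,counts_b per-gene tag counts (same order).
#' @param libsize_a,libsize_b library sizes (> 0); default to the column
#'   totals.
#' @param pseudocount added to both counts before the ratio.
#' @param gene_id optional gene identifiers.
#' @return data frame with `gene_id`, `log2fc`, `pseudocount`.
#' @export
log2_fold_change <- function(counts_a, counts_b,
                             libsize_a = sum(counts_a),
                             libsize_b = sum(counts_b),
                             pseudocount = 1,
                             gene_id = NULL) {
  stopifnot(length(counts_a) == length(counts_b),
            libsize_a > 0, libsize_b > 0, pseudocount >= 0)
  if (is.null(gene_id)) gene_id <- as.character(seq_along(counts_a))
  lfc <- log2(((counts_b + pseudocount) / libsize_b) /
              ((counts_a + pseudocount) / libsize_a))
  data.frame(gene_id = gene_id, log2fc = lfc, pseudocount = pseudocount,
             stringsAsFactors = FALSE)
}

#' Combined RNA/GRO fold-change table
#'
#' Computes per-assay log2 fold changes (condition 2 vs condition 1) and
#' the combined value: the arithmetic mean of the RNA and GRO log2 fold
#' changes when both are available, the RNA value alone otherwise.
#'
#' @param rna_counts data frame: `gene_id` plus two count columns
#'   (condition 1, condition 2).
#' @param gro_counts optional data frame in the same layout.
#' @param pseudocount passed to [log2_fold_change()].
#' @param libsize optional length-2 vector of library sizes shared by both
#'   assays (e.g. a known sequencing depth or spike-in normalizer);
#'   defaults to the per-assay column totals.
#' @return data frame of class `fold_change_table`: `gene_id`,
#'   `log2fc_rna`, `log2fc_gro` (NA when absent), `combined`,
#'   `pseudocount`.
#' @export
fold_change_table <- function(rna_counts, gro_counts = NULL,
                              pseudocount = 1, libsize = NULL) {
  stopifnot(ncol(rna_counts) >= 3)
  ls_a <- if (is.null(libsize)) sum(rna_counts[[2]]) else libsize[1]
  ls_b <- if (is.null(libsize)) sum(rna_counts[[3]]) else libsize[2]
  rna <- log2_fold_change(rna_counts[[2]], rna_counts[[3]],
                          libsize_a = ls_a, libsize_b = ls_b,
                          pseudocount = pseudocount,
                          gene_id = rna_counts$gene_id)
  out <- data.frame(gene_id = rna$gene_id, log2fc_rna = rna$log2fc,
                    log2fc_gro = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(gro_counts)) {
    ls_a <- if (is.null(libsize)) sum(gro_counts[[2]]) else libsize[1]
    ls_b <- if (is.null(libsize)) sum(gro_counts[[3]]) else libsize[2]
    gro <- log2_fold_change(gro_counts[[2]], gro_counts[[3]],
                            libsize_a = ls_a, libsize_b = ls_b,
                            pseudocount = pseudocount,
                            gene_id = gro_counts$gene_id)
    out$log2fc_gro <- gro$log2fc[match(out$gene_id, gro$gene_id)]
  }
  out$combined <- ifelse(is.na(out$log2fc_gro), out$log2fc_rna,
                         (out$log2fc_rna + out$log2fc_gro) / 2)
  out$pseudocount <- pseudocount
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Expressed-gene set from normalized exon density
#'
#' A gene is called expressed when its mean normalized exonic tag density
#' across the two conditions is at least `min_density` tags/kb/10M.
#'
#' @param rna_counts data frame: `gene_id` plus two count columns.
#' @param genes a `gene_models` (for exonic lengths).
#' @param min_density threshold in tags/kb/10M.
#' @return character vector of expressed gene ids.
#' @export
expressed_genes <- function(rna_counts, genes, min_density = 0.5) {
  exkb <- exon_length(genes)[match(rna_counts$gene_id, genes$gene_id)] / 1000
  d1 <- rna_counts[[2]] / exkb / (sum(rna_counts[[2]]) / 1e7)
  d2 <- rna_counts[[3]] / exkb / (sum(rna_counts[[3]]) / 1e7)
  rna_counts$gene_id[(d1 + d2) / 2 >= min_density]
}

#' Classify senescence-regulated gene sets
#'
#' Partitions every input gene into exactly one of `S_GAINED`, `S_LOST`,
#' `UNCHANGED`, `NOT_EXPRESSED`. A gene is `S_GAINED` when its combined
#' fold change is at least `up_thresh` and, if concordance is required and
#' a GRO value exists, the RNA and GRO fold changes do not disagree in
#' sign; `S_LOST` is symmetric.
#'
#' @param fc a `fold_change_table`.
#' @param expressed character vector of expressed gene ids.
#' @param up_thresh,down_thresh log2 thresholds, `down_thresh < 0 <
#'   up_thresh`.
#' @param require_concordance require `sign(rna) == sign(gro)` (a zero on
#'   either side is treated as compatible).
#' @return data frame of class `regulation_calls`: `gene_id`, `label`;
#'   thresholds kept as attributes.
#' @export
classify_regulation <- function(fc, expressed, up_thresh = 1,
                                down_thresh = -1,
                                require_concordance = TRUE) {
  if (!(down_thresh < 0 && 0 < up_thresh))
    stop("need down_thresh < 0 < up_thresh")
  concordant <- if (require_concordance)
    is.na(fc$log2fc_gro) |
      sign(fc$log2fc_rna) * sign(fc$log2fc_gro) >= 0
  else rep(TRUE, nrow(fc))
  label <- rep("UNCHANGED", nrow(fc))
  label[fc$combined >= up_thresh & concordant] <- "S_GAINED"
  label[fc$combined <= down_thresh & concordant] <- "S_LOST"
  label[!(fc$gene_id %in% expressed)] <- "NOT_EXPRESSED"
  out <- data.frame(gene_id = fc$gene_id, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "up_thresh") <- up_thresh
  attr(out, "down_thresh") <- down_thresh
  attr(out, "require_concordance") <- require_concordance
  class(out) <- c("regulation_calls", "data.frame")
  out
}

#' Stratify genes by length
#'
#' Bins are half-open: `[0, e1), [e1, e2), ..., [ek, Inf)`. A length equal
#' to an edge falls in the upper bin. Empty `edges` gives one bin holding
#' every gene.
#'
#' @param genes a `gene_models`.
#' @param edges strictly increasing bin edges in bp. The defaults split at
#'   10, 30 and 100 kb, the conventional short / medium / long / very-long
#'   gene categories.
#' @return data frame with `gene_id`, `gene_length`, `bin` (ordered
#'   factor); edges kept as an attribute.
#' @export
length_stratify <- function(genes, edges = c(10000, 30000, 100000)) {
  if (length(edges) && (is.unsorted(edges, strictly = TRUE) ||
                        any(edges <= 0)))
    stop("edges must be strictly increasing and positive")
  len <- gene_length(genes)
  full <- c(0, edges, Inf)
  labs <- paste0("[", format(full[-length(full)], scientific = FALSE,
                             trim = TRUE), ",",
                 format(full[-1], scientific = FALSE, trim = TRUE), ")")
  bin <- cut(len, breaks = full, labels = labs, right = FALSE,
             include.lowest = TRUE, ordered_result = TRUE)
  out <- data.frame(gene_id = genes$gene_id, gene_length = len, bin = bin,
                    stringsAsFactors = FALSE)
  attr(out, "edges") <- edges
  out
}

#' Pol II pausing index per gene
#'
#' `PI = promoter density / body density`, with the promoter window
#' defaulting to TSS-50..+300 and the body running from TSS+300 to the
#' TES, all normalized densities from the same (nascent-transcription)
#' track so PI is invariant to library scaling. Records are invalid (with
#' a reason) for genes shorter than `body_from + 100` bp or with zero body
#' density.
#'
#' @param track a `coverage_track` (GRO-seq-like nascent signal).
#' @param genes a `gene_models`.
#' @param promoter_window a `genomic_window` for the promoter-proximal
#'   region.
#' @param body_from start of the body region, bp downstream of the TSS.
#' @return data frame of class `pausing_records`: `gene_id`,
#'   `promoter_density`, `body_density`, `pi`, `valid`, `reason`.
#' @export
pausing_index <- function(track, genes,
                          promoter_window = genomic_window("TSS", -50, 300),
                          body_from = 300) {
  n <- nrow(genes)
  len <- gene_length(genes)
  ok_len <- len > body_from + 100
  prom <- body <- rep(NA_real_, n)
  if (any(ok_len)) {
    g <- genes[ok_len, ]
    prom[ok_len] <- window_density(track, g, promoter_window)$norm_density
    body[ok_len] <- gene_body_density(track, g,
                                      promoter_exclusion_bp = body_from)$norm_density
  }
  valid <- ok_len & !is.na(body) & body > 0
  reason <- rep("", n)
  reason[!ok_len] <- "too_short"
  reason[ok_len & !valid] <- "zero_body_density"
  pi <- ifelse(valid, prom / body, NA_real_)
  out <- data.frame(gene_id = genes$gene_id, promoter_density = prom,
                    body_density = body, pi = pi, valid = valid,
                    reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("pausing_records", "data.frame")
  out
}

#' Empirical cumulative pausing-index curve
#'
#' Sorted PI values of the valid records against cumulative fraction; a
#' right-shifted curve means a more paused gene set.
#'
#' @param records a `pausing_records` data frame.
#' @return data frame with `pi` (ascending) and `cum_frac`; number of
#'   invalid records kept as attribute `n_invalid`.
#' @export
pi_curve <- function(records) {
  v <- records$pi[records$valid]
  if (!length(v)) stop("no valid pausing records")
  v <- sort(v)
  out <- data.frame(pi = v, cum_frac = seq_along(v) / length(v))
  attr(out, "n_invalid") <- sum(!records$valid)
  out
}

#' Per-gene change in log2 pausing index between conditions
#'
#' `delta = log2(pi_b) - log2(pi_a)` over genes valid in both conditions;
#' genes invalid in either are excluded and counted.
#'
#' @param records_a,records_b `pausing_records` for the two conditions.
#' @return data frame with `gene_id`, `delta_log2_pi`; attribute
#'   `n_excluded` counts genes dropped.
#' @export
delta_pi <- function(records_a, records_b) {
  common <- intersect(records_a$gene_id[records_a$valid],
                      records_b$gene_id[records_b$valid])
  if (!length(common)) stop("no gene valid in both conditions")
  pa <- records_a$pi[match(common, records_a$gene_id)]
  pb <- records_b$pi[match(common, records_b$gene_id)]
  out <- data.frame(gene_id = common,
                    delta_log2_pi = log2(pb) - log2(pa),
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <-
    length(union(records_a$gene_id, records_b$gene_id)) - length(common)
  out
}
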