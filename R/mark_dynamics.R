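# Histone-mark redistribution between conditions: promoter loss, gene-body
# gain, spreading, and mark-defined gene-set selection.

#' Per-gene mark change between conditions
#'
#' log2 fold change of normalized density in a region (a promoter-style
#' `genomic_window` or the literal `"body"`) between two coverage tracks.
#' The pseudocount (default 0.5 tags/kb/10M) is applied on the normalized
#' densities; zero-signal promoters make it mandatory. Swapping the two
#' tracks negates every value exactly.
#'
#' @param track_a,track_b `coverage_track`s for condition 1 and 2.
#' @param genes a `gene_models`.
#' @param region a `genomic_window`, or `"body"` for the whole gene body.
#' @param pseudocount added to both normalized densities.
#' @param promoter_exclusion_bp passed to [gene_body_density()] when
#'   `region = "body"`.
#' @return data frame of class `mark_change_records`: `gene_id`, `region`,
#'   `density_a`, `density_b`, `log2fc_mark`, `pseudocount`.
#' @export
mark_change <- function(track_a, track_b, genes, region,
                        pseudocount = 0.5, promoter_exclusion_bp = 0) {
  if (identical(region, "body")) {
    da <- gene_body_density(track_a, genes, promoter_exclusion_bp)
    db <- gene_body_density(track_b, genes, promoter_exclusion_bp)
    region_lab <- "gene_body"
  } else {
    stopifnot(inherits(region, "genomic_window"))
    da <- window_density(track_a, genes, region)
    db <- window_density(track_b, genes, region)
    region_lab <- sprintf("%s%+d..%+d", region$anchor, region$rel_start,
                          region$rel_end)
  }
  out <- data.frame(gene_id = genes$gene_id, region = region_lab,
                    density_a = da$norm_density, density_b = db$norm_density,
                    # difference of logs, not log of ratio: exactly
                    # antisymmetric under condition swap
                    log2fc_mark = log2(db$norm_density + pseudocount) -
                      log2(da$norm_density + pseudocount),
                    pseudocount = pseudocount, stringsAsFactors = FALSE)
  class(out) <- c("mark_change_records", "data.frame")
  out
}

#' Select genes by mark change threshold
#'
#' Strict inequality, matching the "< -2.5 log2 fold change" convention:
#' a record exactly at the threshold is excluded in both directions.
#'
#' @param records `mark_change_records`.
#' @param threshold log2 fold-change cutoff.
#' @param direction `"below"` or `"above"`.
#' @return character vector of gene ids.
#' @export
select_by_mark_change <- function(records, threshold,
                                  direction = c("below", "above")) {
  direction <- match.arg(direction)
  if (!nrow(records)) stop("no mark change records")
  keep <- if (direction == "below") records$log2fc_mark < threshold
          else records$log2fc_mark > threshold
  records$gene_id[keep]
}

#' Expression change as a function of mark change
#'
#' Bins genes on their mark log2 fold change and compares each bin's
#' expression log2 fold-change distribution against a reference with a
#' two-tailed two-sample z-test. Bins with fewer than 3 genes are flagged
#' and not tested.
#'
#' The reference can be `"all"` genes shared by both inputs (the
#' all-genes-curve convention: a bin equal to the whole input gives z = 0
#' exactly) or each bin's `"complement"` (disjoint groups, for which the
#' z-test null is calibrated and permutation p-values are uniform). Which
#' was used is recorded in the result.
#'
#' @param mark_records `mark_change_records`.
#' @param fc_records a `fold_change_table`.
#' @param bin_edges increasing edges on the mark change; bins are
#'   `(-Inf, e1), [e1, e2), ..., [ek, Inf)`.
#' @param reference `"all"` (default) or `"complement"`.
#' @return data frame with one row per bin: `bin`, `n`, `median_expr_lfc`,
#'   `mean_expr_lfc`, `z`, `p_value`, `tested`; reference mode, mean and n
#'   kept as attributes.
#' @export
mark_expression_association <- function(mark_records, fc_records,
                                        bin_edges,
                                        reference = c("all", "complement")) {
  reference <- match.arg(reference)
  if (length(bin_edges) < 1 || is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  common <- intersect(mark_records$gene_id, fc_records$gene_id)
  if (!length(common)) stop("no genes shared between mark and expression inputs")
  mk <- mark_records$log2fc_mark[match(common, mark_records$gene_id)]
  ex <- fc_records$combined[match(common, fc_records$gene_id)]
  full <- c(-Inf, bin_edges, Inf)
  labs <- paste0("[", full[-length(full)], ",", full[-1], ")")
  bin <- cut(mk, breaks = full, labels = labs, right = FALSE)
  rows <- lapply(levels(bin), function(b) {
    x <- ex[bin == b]
    ref <- if (reference == "all") ex else ex[bin != b]
    n <- length(x)
    tested <- n >= 3 && length(ref) >= 3
    z <- p <- NA_real_
    if (tested) {
      t <- two_tailed_ztest(x, ref)
      z <- t$statistic; p <- t$p_value
    }
    data.frame(bin = b, n = n,
               median_expr_lfc = if (n) stats::median(x) else NA_real_,
               mean_expr_lfc = if (n) mean(x) else NA_real_,
               z = z, p_value = p, tested = tested,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  attr(out, "reference_n") <- length(ex)
  attr(out, "reference_mean") <- mean(ex)
  out
}

#' Promoter-to-body spreading summary
#'
#' For each gene and condition, the spreading ratio is body density over
#' promoter density; `delta_spreading = log2(ratio_b) - log2(ratio_a)`
#' quantifies redistribution from the promoter into the body between
#' conditions. Genes with zero promoter density in either condition are
#' dropped and counted. Medians of `delta_spreading` are reported per
#' gene-length bin.
#'
#' @inheritParams mark_change
#' @param promoter_window `genomic_window` defining the promoter (shared
#'   with the pausing-index default so one promoter definition serves a
#'   run).
#' @param promoter_exclusion_bp bp excluded from the body at the TSS side.
#' @param length_edges passed to [length_stratify()].
#' @return list with `records` (per-gene data frame), `by_length` (bin,
#'   n, median delta), `n_dropped`.
#' @export
spreading_summary <- function(track_a, track_b, genes,
                              promoter_window = genomic_window("TSS", -50, 300),
                              promoter_exclusion_bp = 300,
                              length_edges = c(10000, 30000, 100000)) {
  pa <- window_density(track_a, genes, promoter_window)$norm_density
  pb <- window_density(track_b, genes, promoter_window)$norm_density
  ba <- gene_body_density(track_a, genes, promoter_exclusion_bp)$norm_density
  bb <- gene_body_density(track_b, genes, promoter_exclusion_bp)$norm_density
  ok <- pa > 0 & pb > 0
  n_dropped <- sum(!ok)
  records <- data.frame(gene_id = genes$gene_id,
                        promoter_a = pa, promoter_b = pb,
                        body_a = ba, body_b = bb,
                        ratio_a = ba / pa, ratio_b = bb / pb,
                        stringsAsFactors = FALSE)[ok, ]
  records$delta_spreading <- log2(records$ratio_b) - log2(records$ratio_a)
  strata <- length_stratify(genes[ok, ], length_edges)
  med <- tapply(records$delta_spreading, strata$bin, stats::median)
  by_length <- data.frame(bin = names(med),
                          n = as.integer(table(strata$bin)[names(med)]),
                          median_delta_spreading = as.numeric(med),
                          stringsAsFactors = FALSE)
  list(records = records, by_length = by_length, n_dropped = n_dropped)
}
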