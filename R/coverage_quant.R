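# Density readouts: window densities, TSS-centered profiles, per-gene
# profile matrices, and scaled gene-body metagene profiles.
#
# The normalization unit everywhere is tags per kb per 10 million library
# tags. Signal is apportioned to bins by exact base overlap (fractional bin
# boundaries are allowed), via the track's cumulative integral.

.norm_density <- function(raw, width_bp, library_size) {
  ifelse(width_bp > 0 & library_size > 0,
         raw / (width_bp / 1000) / (library_size / 1e7),
         0)
}

#' Normalized tag density in a window
#'
#' Computes the raw tag count and the normalized density (tags per kb per
#' 10 million library tags) of a coverage track in a strand-aware window
#' around each gene's anchor.
#'
#' @param track a `coverage_track`.
#' @param genes a `gene_models` object.
#' @param window a `genomic_window` (e.g. the promoter window
#'   `genomic_window("TSS", -300, 200)`).
#' @return data frame with `gene_id`, `raw_tags`, `width_bp`, `norm_density`.
#' @export
window_density <- function(track, genes, window) {
  res <- resolve_window(genes, window)
  w <- res$end - res$start
  if (any(w <= 0))
    stop("window fully clipped away for gene(s): ",
         paste(res$gene_id[w <= 0], collapse = ", "))
  raw <- track_window_sum(track, res$chrom, res$start, res$end)
  data.frame(gene_id = res$gene_id, raw_tags = raw, width_bp = w,
             norm_density = .norm_density(raw, w, track$library_size),
             stringsAsFactors = FALSE)
}

#' Normalized gene-body tag density
#'
#' Density over `[TSS + promoter_exclusion_bp, TES)` in transcribed
#' orientation, i.e. the gene body with an optional promoter-proximal
#' region removed.
#'
#' @inheritParams window_density
#' @param promoter_exclusion_bp bases downstream of the TSS to exclude.
#' @export
gene_body_density <- function(track, genes, promoter_exclusion_bp = 0) {
  # body window runs TSS+excl .. TES; its length varies per gene, so it is
  # resolved directly rather than through a fixed-offset genomic_window
  len <- gene_length(genes)
  bad <- len <= promoter_exclusion_bp
  if (any(bad))
    stop("gene length <= promoter exclusion for: ",
         paste(genes$gene_id[bad], collapse = ", "))
  plus <- genes$strand == "+"
  s <- ifelse(plus, genes$start + promoter_exclusion_bp, genes$start)
  e <- ifelse(plus, genes$end, genes$end - promoter_exclusion_bp)
  w <- e - s
  raw <- track_window_sum(track, genes$chrom, s, e)
  data.frame(gene_id = genes$gene_id, raw_tags = raw, width_bp = w,
             norm_density = .norm_density(raw, w, track$library_size),
             stringsAsFactors = FALSE)
}

# Per-gene binned normalized densities for arbitrary per-gene breakpoints.
# breaks: matrix n_genes x (n_bins+1) of absolute positions, ascending in
# genomic coordinates. Returns matrix n_genes x n_bins in genomic order.
.binned_density <- function(track, chrom, breaks, library_size) {
  n <- nrow(breaks)
  nb <- ncol(breaks) - 1
  out <- matrix(0, n, nb)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    cs <- matrix(track_cumsignal(track, ch, pmax(as.vector(breaks[i, , drop = FALSE]), 0)),
                 nrow = length(i))
    raw <- cs[, -1, drop = FALSE] - cs[, -(nb + 1), drop = FALSE]
    w <- pmax(breaks[i, -1, drop = FALSE], 0) -
      pmax(breaks[i, -(nb + 1), drop = FALSE], 0)
    dens <- matrix(.norm_density(raw, w, library_size), nrow = length(i))
    out[i, ] <- dens
  }
  out
}

#' TSS-centered average density profile
#'
#' Mean normalized density in fixed-width bins centered on the TSS, in
#' transcribed orientation (bin 1 is the most upstream bin on either
#' strand). Genes whose upstream bins are clipped at position 0 are
#' excluded from those bins' means (not from the whole profile).
#'
#' @inheritParams window_density
#' @param flank_bp half-width of the profile in bp; must be divisible by
#'   `bin_bp`.
#' @param bin_bp bin width in bp.
#' @return data frame with `rel_start`, `rel_end` (bp relative to TSS in
#'   transcribed orientation), `mean_density`, `n_genes`.
#' @export
tss_profile <- function(track, genes, flank_bp = 2000, bin_bp = 100) {
  if (nrow(genes) == 0) stop("empty gene list")
  if (flank_bp %% bin_bp != 0)
    stop("flank_bp must be divisible by bin_bp")
  nb <- 2 * flank_bp / bin_bp
  rel <- seq(-flank_bp, flank_bp, by = bin_bp)
  t0 <- tss(genes)
  plus <- genes$strand == "+"
  # absolute breakpoints, ascending in genomic coordinates
  breaks <- matrix(NA_real_, nrow(genes), nb + 1)
  breaks[plus, ] <- outer(t0[plus], rel, `+`)
  if (any(!plus))
    breaks[!plus, ] <- outer(t0[!plus], rev(rel), function(a, b) a - b)
  dens <- .binned_density(track, genes$chrom, breaks, track$library_size)
  # flip minus-strand rows into transcribed orientation
  if (any(!plus)) dens[!plus, ] <- dens[!plus, nb:1, drop = FALSE]
  # a bin is valid unless clipping at 0 shortened it
  valid <- matrix(TRUE, nrow(genes), nb)
  clip_w <- pmax(breaks[, -1, drop = FALSE], 0) -
    pmax(breaks[, -(nb + 1), drop = FALSE], 0)
  full <- clip_w >= bin_bp - 1e-9
  if (any(!plus)) full[!plus, ] <- full[!plus, nb:1, drop = FALSE]
  valid <- full
  n_genes <- colSums(valid)
  mean_density <- ifelse(n_genes > 0,
                         colSums(dens * valid) / pmax(n_genes, 1), NA_real_)
  data.frame(rel_start = rel[-length(rel)], rel_end = rel[-1],
             mean_density = mean_density, n_genes = n_genes)
}

#' Metagene profile over scaled gene bodies
#'
#' Each gene body is split into `n_body_bins` equal-width bins (fractional
#' boundaries; signal apportioned by exact base overlap) in transcribed
#' orientation, flanked by fixed-width upstream and downstream regions of
#' `flank_bp` bp in `n_flank_bins` bins each. Per-gene per-bin normalized
#' densities are averaged across genes. Genes shorter than `n_body_bins`
#' bases are excluded and counted.
#'
#' @inheritParams window_density
#' @param n_body_bins number of scaled bins across the gene body.
#' @param flank_bp width of each fixed flank.
#' @param n_flank_bins number of bins per flank.
#' @return object of class `metagene_profile`: list with `bin_means`
#'   (length `2 * n_flank_bins + n_body_bins`), `bin_region` (factor:
#'   upstream/body/downstream), `n_genes`, `n_excluded`, and the geometry.
#' @export
metagene_profile <- function(track, genes, n_body_bins = 100,
                             flank_bp = 2000, n_flank_bins = 20) {
  len <- gene_length(genes)
  excl <- len < n_body_bins
  n_excluded <- sum(excl)
  genes <- genes[!excl, ]
  if (nrow(genes) == 0) stop("all genes shorter than n_body_bins; none left")
  if (n_excluded > 0)
    message(n_excluded, " gene(s) shorter than ", n_body_bins,
            " bp excluded from metagene")
  len <- gene_length(genes)
  n <- nrow(genes)
  plus <- genes$strand == "+"
  upstream_rel <- seq(-flank_bp, 0, length.out = n_flank_bins + 1)
  body_frac <- seq(0, 1, length.out = n_body_bins + 1)
  down_rel <- seq(0, flank_bp, length.out = n_flank_bins + 1)
  nb <- 2 * n_flank_bins + n_body_bins
  # breakpoints in transcribed orientation, then mapped to genomic coords
  tr_breaks <- matrix(NA_real_, n, nb + 1)
  tr_breaks[, 1:(n_flank_bins + 1)] <-
    outer(rep(1, n), upstream_rel)                      # relative to TSS
  tr_breaks[, (n_flank_bins + 1):(n_flank_bins + n_body_bins + 1)] <-
    len %o% body_frac                                   # relative to TSS
  tr_breaks[, (n_flank_bins + n_body_bins + 1):(nb + 1)] <-
    len + rep(1, n) %o% down_rel                        # TES + flank
  t0 <- tss(genes)
  breaks <- matrix(NA_real_, n, nb + 1)
  breaks[plus, ] <- t0[plus] + tr_breaks[plus, , drop = FALSE]
  if (any(!plus))
    breaks[!plus, ] <- (t0[!plus] - tr_breaks[!plus, , drop = FALSE])[,
                          (nb + 1):1, drop = FALSE]
  dens <- .binned_density(track, genes$chrom, breaks, track$library_size)
  if (any(!plus)) dens[!plus, ] <- dens[!plus, nb:1, drop = FALSE]
  structure(list(
    bin_means = colMeans(dens),
    bin_region = factor(rep(c("upstream", "body", "downstream"),
                            c(n_flank_bins, n_body_bins, n_flank_bins)),
                        levels = c("upstream", "body", "downstream")),
    n_body_bins = n_body_bins, n_flank_bins = n_flank_bins,
    flank_bp = flank_bp, n_genes = n, n_excluded = n_excluded,
    label = track$label), class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf(
    "<metagene_profile> '%s': %d genes (%d excluded), %d body bins + 2 x %d flank bins (%d bp flanks)\n",
    x$label, x$n_genes, x$n_excluded, x$n_body_bins, x$n_flank_bins,
    x$flank_bp))
  invisible(x)
}

#' Convert a metagene profile to a data frame
#' @param x a `metagene_profile`.
#' @param ... unused.
#' @export
as.data.frame.metagene_profile <- function(x, ...) {
  data.frame(bin = seq_along(x$bin_means), region = x$bin_region,
             mean_density = x$bin_means)
}

#' Per-gene density matrix around an anchor window
#'
#' One row per gene, fixed-width bins spanning the anchor window in
#' transcribed orientation. When `sort_window` is given, rows are ordered
#' by descending density in that window; ties are broken by `gene_id`
#' ascending. This is the matrix behind TSS-anchored heatmaps.
#'
#' @inheritParams window_density
#' @param anchor_window a `genomic_window` spanning the columns (e.g.
#'   `genomic_window("TSS", -3000, 3000)`).
#' @param bin_bp column bin width; the window must span at least one bin.
#' @param sort_window optional `genomic_window` used to order rows (e.g.
#'   `genomic_window("TSS", -500, 200)`).
#' @return object of class `profile_matrix`: list with `matrix` (rows named
#'   by gene_id), `rel_start`, `rel_end`, and `sort_density` when sorted.
#' @export
profile_matrix <- function(track, genes, anchor_window, bin_bp = 50,
                           sort_window = NULL) {
  stopifnot(inherits(anchor_window, "genomic_window"))
  span <- anchor_window$rel_end - anchor_window$rel_start
  nb <- floor(span / bin_bp)
  if (nb < 1) stop("anchor window must span at least one bin")
  rel <- anchor_window$rel_start + bin_bp * (0:nb)
  anchor_pos <- switch(anchor_window$anchor, TSS = tss(genes),
                       TES = tes(genes),
                       absolute = rep(0, nrow(genes)))
  plus <- genes$strand == "+" | anchor_window$anchor == "absolute"
  breaks <- matrix(NA_real_, nrow(genes), nb + 1)
  breaks[plus, ] <- outer(anchor_pos[plus], rel, `+`)
  if (any(!plus))
    breaks[!plus, ] <- outer(anchor_pos[!plus], rev(rel), function(a, b) a - b)
  dens <- .binned_density(track, genes$chrom, breaks, track$library_size)
  if (any(!plus)) dens[!plus, ] <- dens[!plus, nb:1, drop = FALSE]
  rownames(dens) <- genes$gene_id
  sort_density <- NULL
  if (!is.null(sort_window)) {
    sd <- window_density(track, genes, sort_window)
    ord <- order(-sd$norm_density, sd$gene_id)
    dens <- dens[ord, , drop = FALSE]
    sort_density <- sd$norm_density[ord]
    names(sort_density) <- sd$gene_id[ord]
  }
  structure(list(matrix = dens, rel_start = rel[-length(rel)],
                 rel_end = rel[-1], sort_density = sort_density,
                 label = track$label), class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> '%s': %d genes x %d bins (%+d..%+d bp)\n",
              x$label, nrow(x$matrix), ncol(x$matrix),
              x$rel_start[1], x$rel_end[length(x$rel_end)]))
  invisible(x)
}

#' Write a profile or matrix as TSV
#'
#' Deterministic column and row order; bin coordinates in the header.
#' @param x `metagene_profile`, `profile_matrix`, or data frame.
#' @param path output path.
#' @export
write_profile <- function(x, path) {
  if (inherits(x, "metagene_profile")) x <- as.data.frame(x)
  if (inherits(x, "profile_matrix")) {
    df <- data.frame(gene_id = rownames(x$matrix), x$matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene_id", paste0("bin_", x$rel_start, "_", x$rel_end))
    x <- df
  }
  write_tsv_sorted(x, path, sort = FALSE)
}

# shared deterministic TSV writer
write_tsv_sorted <- function(df, path, sort = TRUE, key = NULL) {
  if (sort) {
    if (is.null(key)) key <- intersect(c("chrom", "start", "gene_id"),
                                       colnames(df))
    if (length(key)) df <- df[do.call(order, df[key]), , drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
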