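# Synthetic two-condition senescence dataset with planted effects.
#
# The generator states a world resembling the biology being quantified:
# log-normal gene lengths; a planted upregulated (GAINED) set biased toward
# long genes; a planted downregulated (LOST) set; expression counts over
# exons (RNA-like) and bodies (GRO-like) with concordant planted fold
# changes; histone-mark coverage with a Gaussian promoter peak plus a body
# level that can spread with gene length; and promoter mark loss coupled to
# induction. All outputs are deterministic under one master seed, with
# per-track child seeds derived by stable string hashing so adding a track
# never perturbs existing ones.

#' Shape of one mark in one condition
#'
#' @param promoter_amplitude peak per-base signal at the TSS, relative to
#'   `body_level` units.
#' @param promoter_width_bp Gaussian sigma of the promoter peak.
#' @param body_level uniform per-base signal over the gene body.
#' @param spread_coefficient body gain per log10 length: the body level is
#'   multiplied by `1 + spread_coefficient * log10(gene_length)`.
#' @export
mark_shape <- function(promoter_amplitude, promoter_width_bp = 250,
                       body_level = 1, spread_coefficient = 0) {
  stopifnot(promoter_amplitude >= 0, promoter_width_bp > 0,
            body_level >= 0)
  list(promoter_amplitude = promoter_amplitude,
       promoter_width_bp = promoter_width_bp,
       body_level = body_level,
       spread_coefficient = spread_coefficient)
}

#' Default mark shapes
#'
#' Two marks spanning the two phenomena the pipeline quantifies:
#' `H3K79me3` is promoter-proximally enriched in the early-passage
#' quiescent (EPQ) condition and spreads into gene bodies (length-dependent
#' body gain) in the senescent (SEN) condition; `H4R3me2s` is a strong
#' promoter mark in both conditions, and loses promoter signal at induced
#' genes through `mark_loss_coupling` (see [synthetic_config()]).
#' The EPQ H3K79me3 shape puts most of each gene's mark mass
#' promoter-proximal (peak mass a few-fold the body mass), so that after
#' equal-depth library normalization the senescent body gain remains
#' visible as an absolute rise in normalized body density.
#' @export
default_mark_shapes <- function() {
  list(
    H3K79me3 = list(
      EPQ = mark_shape(60, 150, body_level = 0.1, spread_coefficient = 0),
      SEN = mark_shape(60, 150, body_level = 0.1, spread_coefficient = 1.0)),
    H4R3me2s = list(
      EPQ = mark_shape(10, 250, body_level = 0.1, spread_coefficient = 0),
      SEN = mark_shape(10, 250, body_level = 0.1, spread_coefficient = 0)))
}

#' Configuration of the synthetic dataset
#'
#' Defaults state the structure reported for replicative senescence:
#' upregulated genes markedly longer (`gained_length_bias = 3`), a planted
#' 2 log2-unit expression effect, promoter mark loss of 5 log2 units at
#' induced genes, and Poisson tag noise at 1e6 tags per track.
#'
#' @param n_genes number of genes (>= 10).
#' @param length_meanlog,length_sdlog log-normal gene-length parameters
#'   (natural log of bp).
#' @param frac_gained,frac_lost fractions planted up/down; sum <= 1.
#' @param gained_length_bias multiplicative length shift of GAINED genes.
#' @param lost_length_bias multiplicative length shift of LOST genes.
#' @param expr_effect planted |log2 fold change| for regulated sets.
#' @param mark_shapes nested list `mark -> condition -> mark_shape`.
#' @param mark_loss_coupling log2 change applied to the promoter amplitude
#'   of GAINED genes in condition 2, for `coupled_mark` only.
#' @param coupled_mark which mark receives `mark_loss_coupling`.
#' @param conditions two condition names; the second is the senescent-like
#'   state where planted effects appear.
#' @param noise `"poisson"` or `"negative_binomial"`.
#' @param nb_dispersion NB dispersion (var = mu + dispersion * mu^2).
#' @param depth expected tags per mark track.
#' @param expr_depth expected tags per expression library.
#' @param min_gap minimum intergenic gap in bp (>= 10 kb keeps window
#'   clipping and overlap edge cases testable on one synthetic chromosome).
#' @param track_bin_bp discretization of mark tracks.
#' @param seed master seed; child seeds are derived per output.
#' @export
synthetic_config <- function(n_genes = 2000,
                             length_meanlog = log(20000),
                             length_sdlog = 1.0,
                             frac_gained = 0.1, frac_lost = 0.1,
                             gained_length_bias = 3,
                             lost_length_bias = 1,
                             expr_effect = 2,
                             mark_shapes = default_mark_shapes(),
                             mark_loss_coupling = -5,
                             coupled_mark = "H4R3me2s",
                             conditions = c("EPQ", "SEN"),
                             noise = c("poisson", "negative_binomial"),
                             nb_dispersion = 0.2,
                             depth = 1e6, expr_depth = 1e6,
                             min_gap = 10000, track_bin_bp = 50,
                             seed = 1) {
  noise <- match.arg(noise)
  if (n_genes < 10) stop("n_genes must be >= 10")
  if (frac_gained < 0 || frac_lost < 0 || frac_gained + frac_lost > 1)
    stop("fractions must be in [0,1] with frac_gained + frac_lost <= 1")
  if (length(conditions) != 2) stop("exactly two conditions required")
  stopifnot(gained_length_bias > 0, lost_length_bias > 0, depth >= 0,
            expr_depth >= 0, min_gap >= 0, track_bin_bp >= 1)
  structure(list(n_genes = n_genes, length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog, frac_gained = frac_gained,
                 frac_lost = frac_lost,
                 gained_length_bias = gained_length_bias,
                 lost_length_bias = lost_length_bias,
                 expr_effect = expr_effect, mark_shapes = mark_shapes,
                 mark_loss_coupling = mark_loss_coupling,
                 coupled_mark = coupled_mark, conditions = conditions,
                 noise = noise, nb_dispersion = nb_dispersion,
                 depth = depth, expr_depth = expr_depth, min_gap = min_gap,
                 track_bin_bp = track_bin_bp, seed = seed),
            class = "synthetic_config")
}

#' Derive a child seed from a master seed and a label
#'
#' Stable (platform-independent) string hash folded into `[0, 2^31 - 2]`.
#' Each output (gene set, count table, each mark/condition track) draws
#' from its own child stream, so adding a track never changes another.
#'
#' @param seed integer master seed.
#' @param label character label of the stream.
#' @export
child_seed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Generate gene models with ground-truth labels
#'
#' Lengths are log-normal; GAINED (LOST) genes' lengths are multiplied by
#' `gained_length_bias` (`lost_length_bias`). Genes are placed
#' non-overlapping on one synthetic chromosome (`chrS`) with intergenic
#' gaps of at least `min_gap` bp, alternating strands at random.
#'
#' @param config a `synthetic_config`.
#' @return list with `genes` (a `gene_models`) and `truth` (data frame:
#'   `gene_id`, `label` in GAINED/LOST/UNCHANGED, `true_expr_log2fc`,
#'   `true_promoter_log2fc`, `true_body_log2fc`).
#' @export
generate_genes <- function(config) {
  withr_seed <- child_seed(config$seed, "genes")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)
  n <- config$n_genes
  n_g <- round(n * config$frac_gained)
  n_l <- round(n * config$frac_lost)
  label <- rep("UNCHANGED", n)
  idx <- sample.int(n, n_g + n_l)
  label[idx[seq_len(n_g)]] <- "GAINED"
  if (n_l > 0) label[idx[n_g + seq_len(n_l)]] <- "LOST"
  len <- stats::rlnorm(n, config$length_meanlog, config$length_sdlog)
  len[label == "GAINED"] <- len[label == "GAINED"] * config$gained_length_bias
  len[label == "LOST"] <- len[label == "LOST"] * config$lost_length_bias
  len <- pmax(round(len), 200)
  gaps <- round(stats::runif(n, config$min_gap, 2 * config$min_gap))
  start <- 50000 + cumsum(c(0, len[-n] + gaps[-n]))
  end <- start + len
  strand <- sample(c("+", "-"), n, replace = TRUE)
  # exons: k evenly spaced blocks covering ~40% of the body
  k <- pmin(pmax(1 + stats::rpois(n, 4), 1), 20)
  exons <- vector("list", n)
  for (i in seq_len(n)) {
    ki <- min(k[i], floor(len[i] / 60))
    ki <- max(ki, 1)
    elen <- max(floor(len[i] * 0.4 / ki), 20)
    step <- floor(len[i] / ki)
    s <- start[i] + step * (seq_len(ki) - 1)
    exons[[i]] <- cbind(start = s, end = pmin(s + elen, end[i]))
  }
  gene_id <- sprintf("G%05d", seq_len(n))
  genes <- gene_models(gene_id, chrom = "chrS", strand = strand,
                       start = start, end = end, exons = exons,
                       biotype = "protein_coding")
  expr_fc <- ifelse(label == "GAINED", config$expr_effect,
                    ifelse(label == "LOST", -config$expr_effect, 0))
  # truth for the coupled promoter mark and the spreading body mark
  prom_fc <- ifelse(label == "GAINED", config$mark_loss_coupling, 0)
  body_fc <- .true_body_log2fc(config, len)
  truth <- data.frame(gene_id = gene_id, label = label,
                      true_expr_log2fc = expr_fc,
                      true_promoter_log2fc = prom_fc,
                      true_body_log2fc = body_fc,
                      stringsAsFactors = FALSE)
  list(genes = genes, truth = truth)
}

.true_body_log2fc <- function(config, len) {
  sh <- config$mark_shapes[["H3K79me3"]]
  if (is.null(sh)) return(rep(0, length(len)))
  c1 <- sh[[config$conditions[1]]]
  c2 <- sh[[config$conditions[2]]]
  b1 <- c1$body_level * (1 + c1$spread_coefficient * log10(len))
  b2 <- c2$body_level * (1 + c2$spread_coefficient * log10(len))
  log2(pmax(b2, .Machine$double.xmin) / pmax(b1, .Machine$double.xmin))
}

# save/restore the global RNG state so generator calls are reproducible
# without disturbing the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

.draw_counts <- function(mu, config) {
  if (config$noise == "poisson") stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
}

#' Generate RNA-like and GRO-like count tables
#'
#' Baseline expression is proportional to (exonic or body) length times a
#' log-normal per-gene level shared between the two assays, so RNA and GRO
#' effects are concordant in sign. Condition-1 means are normalized to
#' `expr_depth` expected tags; condition-2 means are the condition-1 means
#' scaled by `2^(+/- expr_effect)` for planted sets (the condition-2
#' library is therefore larger when induction dominates, as in a real
#' spike-in-normalized experiment), and counts are drawn under the noise
#' model. Fold changes computed against equal library sizes of
#' `expr_depth` recover the planted effects without composition bias.
#'
#' @param genes,truth output of [generate_genes()].
#' @param config a `synthetic_config`.
#' @return list of two data frames `rna` and `gro`, each `gene_id` plus one
#'   count column per condition.
#' @export
generate_expression_counts <- function(genes, truth, config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(config$seed, "expr_levels"))
  level <- stats::rlnorm(nrow(genes), 0, 1)
  fc_mult <- 2^truth$true_expr_log2fc
  tables <- list()
  for (assay in c("rna", "gro")) {
    w1 <- if (assay == "rna") exon_length(genes) * level
          else gene_length(genes) * level
    mu1 <- config$expr_depth * w1 / sum(w1)
    mu2 <- mu1 * fc_mult
    set.seed(child_seed(config$seed, paste0("counts_", assay)))
    df <- data.frame(gene_id = genes$gene_id,
                     c1 = .draw_counts(mu1, config),
                     c2 = .draw_counts(mu2, config),
                     stringsAsFactors = FALSE)
    colnames(df) <- c("gene_id", config$conditions)
    tables[[assay]] <- df
  }
  tables
}

#' Generate one histone-mark coverage track
#'
#' Expected per-base signal per gene is a Gaussian promoter peak at the TSS
#' (amplitude, sigma from the mark shape; strand-aware) plus a uniform body
#' level scaled by `1 + spread_coefficient * log10(length)`. For the
#' coupled mark in condition 2, `2^mark_loss_coupling` multiplies the
#' promoter amplitude of GAINED genes. Expected signal is discretized into
#' `track_bin_bp` bins, globally rescaled to `depth` expected tags, and
#' tags are drawn per bin under the noise model.
#'
#' @inheritParams generate_expression_counts
#' @param mark mark name (must exist in `config$mark_shapes`).
#' @param condition condition name (must exist under that mark).
#' @return a `coverage_track` labelled `"<mark>_<condition>"`, with
#'   `library_size` equal to the realized total tags.
#' @export
generate_mark_track <- function(genes, truth, config, mark, condition) {
  shapes <- config$mark_shapes[[mark]]
  if (is.null(shapes) || is.null(shapes[[condition]]))
    stop("no mark shape configured for (", mark, ", ", condition, ")")
  sh <- shapes[[condition]]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(config$seed, paste0("track_", mark, "_", condition)))
  binw <- config$track_bin_bp
  is_cond2 <- condition == config$conditions[2]
  coupled <- mark == config$coupled_mark & is_cond2
  n <- nrow(genes)
  len <- gene_length(genes)
  t0 <- tss(genes)
  amp <- rep(sh$promoter_amplitude, n)
  if (coupled)
    amp[truth$label == "GAINED"] <- amp[truth$label == "GAINED"] *
      2^config$mark_loss_coupling
  body <- sh$body_level * (1 + sh$spread_coefficient * log10(len))
  sigma <- sh$promoter_width_bp
  pad <- ceiling(4 * sigma / binw) * binw
  starts <- ends <- mus <- vector("list", n)
  for (i in seq_len(n)) {
    lo <- max(genes$start[i] - pad, 0)
    hi <- genes$end[i] + pad
    bs <- seq(floor(lo / binw) * binw, hi, by = binw)
    be <- bs + binw
    # promoter Gaussian mass per bin (exact via normal CDF)
    prom <- amp[i] * sigma * sqrt(2 * pi) *
      (stats::pnorm(be, t0[i], sigma) - stats::pnorm(bs, t0[i], sigma))
    # uniform body mass per bin (exact overlap with [start, end))
    ov <- pmax(pmin(be, genes$end[i]) - pmax(bs, genes$start[i]), 0)
    mu <- prom + body[i] * ov
    keep <- mu > 1e-12
    starts[[i]] <- bs[keep]; ends[[i]] <- be[keep]; mus[[i]] <- mu[keep]
  }
  bs <- unlist(starts); be <- unlist(ends); mu <- unlist(mus)
  if (config$depth > 0 && sum(mu) > 0) mu <- mu * config$depth / sum(mu)
  tags <- .draw_counts(mu, config)
  keep <- tags > 0
  # value is per-base density so that the window integral equals tag count
  coverage_track(rep("chrS", sum(keep)), bs[keep], be[keep],
                 tags[keep] / binw,
                 label = paste0(mark, "_", condition))
}

#' Generate and optionally write a complete synthetic dataset
#'
#' Runs [generate_genes()], [generate_expression_counts()] and
#' [generate_mark_track()] for every configured mark and condition. When
#' `outdir` is given, writes `genes.bed`, `<mark>_<condition>.bedGraph`,
#' `rna_counts.tsv`, `gro_counts.tsv`, `ground_truth.tsv` and
#' `config.yaml`, all byte-deterministic under the config seed.
#'
#' @param config a `synthetic_config`.
#' @param outdir optional output directory (created if missing).
#' @param tracks generate coverage tracks (set `FALSE` to skip the
#'   expensive part when only counts are needed).
#' @return list with `genes`, `truth`, `counts`, `tracks`, `config`.
#' @export
simulate_dataset <- function(config, outdir = NULL, tracks = TRUE) {
  gen <- generate_genes(config)
  counts <- generate_expression_counts(gen$genes, gen$truth, config)
  trk <- list()
  if (tracks) {
    for (mark in names(config$mark_shapes))
      for (cond in names(config$mark_shapes[[mark]])) {
        trk[[paste0(mark, "_", cond)]] <-
          generate_mark_track(gen$genes, gen$truth, config, mark, cond)
      }
  }
  out <- list(genes = gen$genes, truth = gen$truth, counts = counts,
              tracks = trk, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_gene_models(gen$genes, file.path(outdir, "genes.bed"))
    write_tsv_sorted(counts$rna, file.path(outdir, "rna_counts.tsv"),
                     key = "gene_id")
    write_tsv_sorted(counts$gro, file.path(outdir, "gro_counts.tsv"),
                     key = "gene_id")
    write_tsv_sorted(gen$truth, file.path(outdir, "ground_truth.tsv"),
                     key = "gene_id")
    for (nm in names(trk))
      write_coverage(trk[[nm]], file.path(outdir, paste0(nm, ".bedGraph")))
    cfg <- config; class(cfg) <- NULL
    yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  }
  invisible(out)
}
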