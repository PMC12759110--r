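# End-to-end orchestration: simulate -> quantify -> classify -> markshift
# -> stats, from a single config, with logging and deterministic outputs.

#' Default run configuration
#'
#' Every tunable of the pipeline in one list: an embedded
#' [synthetic_config()] (or paths to real inputs), window definitions,
#' thresholds, and length-bin edges. All defaults are written into the run
#' manifest so every run is self-describing.
#'
#' @param seed master seed.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    synthetic = synthetic_config(seed = seed),
    inputs = NULL,  # or list(genes=, rna_counts=, gro_counts=, tracks=list())
    promoter_window = c(-300, 200),
    pausing_promoter_window = c(-50, 300),
    pausing_body_from = 300,
    up_thresh = 1, down_thresh = -1,
    require_concordance = TRUE,
    expressed_min_density = 0.5,
    mark_pseudocount = 0.5,
    mark_loss_threshold = -2.5,
    length_edges = c(10000, 30000, 100000),
    spreading_mark = "H3K79me3",
    coupled_mark = "H4R3me2s",
    metagene = list(n_body_bins = 100, flank_bp = 2000, n_flank_bins = 20)
  )
}

#' Read a run configuration from YAML
#'
#' Fields missing from the file are filled with [default_run_config()]
#' values; an embedded `synthetic:` block is promoted to a
#' [synthetic_config()].
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = raw$seed %||% 1)
  for (nm in names(raw)) {
    if (nm == "synthetic") {
      cfg$synthetic <- do.call(synthetic_config, raw$synthetic)
    } else cfg[[nm]] <- raw[[nm]]
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a run configuration
#'
#' Returns a character vector of problems (empty means valid); nothing is
#' raised, so callers can report all problems at once.
#'
#' @param config a run-config list (see [default_run_config()]).
#' @export
validate_config <- function(config) {
  problems <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  need(!is.null(config$seed) && is.finite(config$seed), "seed must be finite")
  need(config$up_thresh > 0, "up_thresh must be > 0")
  need(config$down_thresh < 0, "down_thresh must be < 0")
  for (w in c("promoter_window", "pausing_promoter_window")) {
    win <- config[[w]]
    need(length(win) == 2 && win[1] < win[2],
         paste0(w, " must be (rel_start, rel_end) with rel_start < rel_end"))
  }
  edges <- config$length_edges
  if (length(edges) &&
      (is.unsorted(edges, strictly = TRUE) || any(edges <= 0)))
    problems <- c(problems, "length_edges must be strictly increasing and positive")
  for (th in c("up_thresh", "down_thresh", "mark_loss_threshold",
               "expressed_min_density", "mark_pseudocount"))
    need(is.finite(config[[th]]), paste0(th, " must be finite"))
  if (is.null(config$synthetic) && is.null(config$inputs))
    problems <- c(problems, "either synthetic config or inputs must be given")
  if (!is.null(config$inputs)) {
    for (f in unlist(config$inputs))
      if (is.character(f) && !file.exists(f))
        problems <- c(problems, paste0("missing input file: ", f))
  }
  problems
}

.log_line <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full pipeline
#'
#' Stages, in dependency order: `simulate` (or load inputs), `quantify`
#' (promoter/body densities, metagene profiles), `classify` (fold changes
#' and regulation calls), `pause` (pausing indices and delta-PI),
#' `markshift` (mark changes, selection, spreading,
#' mark-expression association), `stats` (length Mann-Whitney tests and
#' overlap enrichment against ground truth when available). All tables
#' are written with deterministic row and column order; a manifest with
#' config echo and per-file MD5 hashes makes determinism checkable.
#'
#' @param config run-config list; validated first (all problems reported).
#' @param outdir output directory, created if missing.
#' @param stages subset of stages to run (dependency closure is on the
#'   caller; earlier outputs are reused from memory only).
#' @return the run manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "quantify", "classify",
                                    "pause", "markshift", "stats")) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(logcon))
  t_start <- Sys.time()
  manifest <- list(config = .config_echo(config),
                   version = as.character(utils::packageVersion("senespread")),
                   stages = stages, exclusions = list(), files = list())
  conds <- if (!is.null(config$synthetic)) config$synthetic$conditions
           else c("a", "b")
  data <- NULL

  if ("simulate" %in% stages && !is.null(config$synthetic)) {
    .log_line(logcon, "[simulate] generating synthetic dataset (seed ",
              config$synthetic$seed, ")")
    data <- simulate_dataset(config$synthetic, outdir = file.path(outdir, "data"))
  } else if (!is.null(config$inputs)) {
    .log_line(logcon, "[load] reading inputs")
    inp <- config$inputs
    data <- list(genes = read_gene_models(inp$genes),
                 counts = list(
                   rna = as.data.frame(data.table::fread(inp$rna_counts)),
                   gro = if (!is.null(inp$gro_counts))
                     as.data.frame(data.table::fread(inp$gro_counts))),
                 tracks = lapply(inp$tracks, read_coverage),
                 truth = NULL)
  }
  if (is.null(data)) stop("stage 'simulate' skipped but no inputs given")
  genes <- data$genes

  prom_win <- genomic_window("TSS", config$promoter_window[1],
                             config$promoter_window[2])
  pi_win <- genomic_window("TSS", config$pausing_promoter_window[1],
                           config$pausing_promoter_window[2])

  if ("quantify" %in% stages && length(data$tracks)) {
    .log_line(logcon, "[quantify] densities and metagene profiles for ",
              length(data$tracks), " track(s)")
    dens <- lapply(names(data$tracks), function(nm) {
      tr <- data$tracks[[nm]]
      pw <- window_density(tr, genes, prom_win)
      bd <- gene_body_density(tr, genes)
      data.frame(track = nm, gene_id = pw$gene_id,
                 promoter_density = pw$norm_density,
                 body_density = bd$norm_density, stringsAsFactors = FALSE)
    })
    write_tsv_sorted(do.call(rbind, dens),
                     file.path(outdir, "densities.tsv"),
                     key = c("track", "gene_id"))
    mg <- lapply(names(data$tracks), function(nm) {
      prof <- suppressMessages(metagene_profile(
        data$tracks[[nm]], genes,
        n_body_bins = config$metagene$n_body_bins,
        flank_bp = config$metagene$flank_bp,
        n_flank_bins = config$metagene$n_flank_bins))
      manifest$exclusions[[paste0("metagene_short_genes_", nm)]] <<-
        prof$n_excluded
      cbind(track = nm, as.data.frame(prof))
    })
    write_tsv_sorted(do.call(rbind, mg),
                     file.path(outdir, "metagene_profiles.tsv"),
                     key = c("track", "bin"))
  }

  calls <- NULL
  fc <- NULL
  if ("classify" %in% stages && !is.null(data$counts)) {
    # synthetic counts come with a known true depth; using it as the
    # library size for both conditions avoids composition bias in the
    # fold changes (spike-in-style normalization)
    libsize <- if (!is.null(config$synthetic))
      rep(config$synthetic$expr_depth, 2)
    fc <- fold_change_table(data$counts$rna, data$counts$gro,
                            libsize = libsize)
    expressed <- expressed_genes(data$counts$rna, genes,
                                 config$expressed_min_density)
    calls <- classify_regulation(fc, expressed,
                                 up_thresh = config$up_thresh,
                                 down_thresh = config$down_thresh,
                                 require_concordance = config$require_concordance)
    .log_line(logcon, "[classify] ", sum(calls$label == "S_GAINED"),
              " S_GAINED, ", sum(calls$label == "S_LOST"), " S_LOST, ",
              sum(calls$label == "UNCHANGED"), " unchanged, ",
              sum(calls$label == "NOT_EXPRESSED"), " not expressed")
    write_tsv_sorted(as.data.frame(fc), file.path(outdir, "fold_changes.tsv"),
                     key = "gene_id")
    write_tsv_sorted(as.data.frame(calls),
                     file.path(outdir, "regulation_calls.tsv"),
                     key = "gene_id")
  }

  if ("pause" %in% stages && length(data$tracks)) {
    # with synthetic data no dedicated GRO coverage track is simulated, so
    # pausing runs on the spreading mark's two condition tracks
    nm <- grep(paste0("^", config$spreading_mark, "_"),
               names(data$tracks), value = TRUE)
    if (length(nm) == 2) {
      rec_a <- pausing_index(data$tracks[[nm[1]]], genes, pi_win,
                             config$pausing_body_from)
      rec_b <- pausing_index(data$tracks[[nm[2]]], genes, pi_win,
                             config$pausing_body_from)
      dpi <- delta_pi(rec_a, rec_b)
      manifest$exclusions$pausing_invalid <-
        sum(!rec_a$valid) + sum(!rec_b$valid)
      .log_line(logcon, "[pause] ", nrow(dpi), " genes valid in both ",
                "conditions; ", manifest$exclusions$pausing_invalid,
                " invalid record(s)")
      write_tsv_sorted(rbind(cbind(condition = conds[1], as.data.frame(rec_a)),
                             cbind(condition = conds[2], as.data.frame(rec_b))),
                       file.path(outdir, "pausing.tsv"),
                       key = c("condition", "gene_id"))
      write_tsv_sorted(dpi, file.path(outdir, "delta_pi.tsv"), key = "gene_id")
    }
  }

  if ("markshift" %in% stages && length(data$tracks)) {
    marks <- unique(sub("_[^_]+$", "", names(data$tracks)))
    mk_rows <- list()
    for (mark in marks) {
      ta <- data$tracks[[paste0(mark, "_", conds[1])]]
      tb <- data$tracks[[paste0(mark, "_", conds[2])]]
      if (is.null(ta) || is.null(tb)) next
      for (reg in list(prom_win, "body")) {
        mc <- mark_change(ta, tb, genes, reg,
                          pseudocount = config$mark_pseudocount)
        mk_rows[[length(mk_rows) + 1]] <- cbind(mark = mark,
                                                as.data.frame(mc))
      }
    }
    mk <- do.call(rbind, mk_rows)
    write_tsv_sorted(mk, file.path(outdir, "mark_changes.tsv"),
                     key = c("mark", "region", "gene_id"))
    .log_line(logcon, "[markshift] ", length(mk_rows),
              " mark/region combination(s)")
    sp_mark <- config$spreading_mark
    ta <- data$tracks[[paste0(sp_mark, "_", conds[1])]]
    tb <- data$tracks[[paste0(sp_mark, "_", conds[2])]]
    if (!is.null(ta) && !is.null(tb)) {
      sp <- spreading_summary(ta, tb, genes, pi_win,
                              config$pausing_body_from,
                              config$length_edges)
      manifest$exclusions$spreading_zero_promoter <- sp$n_dropped
      .log_line(logcon, "[markshift] spreading: ", sp$n_dropped,
                " gene(s) dropped for zero promoter density")
      write_tsv_sorted(sp$records, file.path(outdir, "spreading.tsv"),
                       key = "gene_id")
      write_tsv_sorted(sp$by_length,
                       file.path(outdir, "spreading_by_length.tsv"),
                       key = NULL, sort = FALSE)
    }
    cp_mark <- config$coupled_mark
    ta <- data$tracks[[paste0(cp_mark, "_", conds[1])]]
    tb <- data$tracks[[paste0(cp_mark, "_", conds[2])]]
    if (!is.null(ta) && !is.null(tb) && !is.null(fc)) {
      mc <- mark_change(ta, tb, genes, prom_win,
                        pseudocount = config$mark_pseudocount)
      assoc <- mark_expression_association(mc, fc,
                                           bin_edges = c(-2.5, -1, 0))
      write_tsv_sorted(assoc, file.path(outdir, "association_report.tsv"),
                       key = NULL, sort = FALSE)
    }
  }

  if ("stats" %in% stages && !is.null(calls)) {
    strata <- length_stratify(genes, config$length_edges)
    len <- stats::setNames(strata$gene_length, strata$gene_id)
    rows <- list()
    for (set in c("S_GAINED", "S_LOST")) {
      ids <- calls$gene_id[calls$label == set]
      ref <- calls$gene_id[calls$label == "UNCHANGED"]
      if (length(ids) >= 1 && length(ref) >= 1) {
        mw <- mann_whitney_u(len[ids], len[ref])
        rows[[set]] <- data.frame(test = "mann_whitney_length",
                                  groups = paste0(set, "_vs_UNCHANGED"),
                                  n_x = mw$n[1], n_y = mw$n[2],
                                  statistic = mw$statistic,
                                  p_value = mw$p_value,
                                  stringsAsFactors = FALSE)
      }
    }
    if (!is.null(data$truth)) {
      for (set in c("S_GAINED", "S_LOST")) {
        truth_lab <- if (set == "S_GAINED") "GAINED" else "LOST"
        fr <- fisher_overlap(calls$gene_id[calls$label == set],
                             data$truth$gene_id[data$truth$label == truth_lab],
                             universe = genes$gene_id)
        rows[[paste0("fisher_", set)]] <-
          data.frame(test = "fisher_overlap_truth",
                     groups = paste0(set, "_vs_", truth_lab),
                     n_x = fr$a + fr$b, n_y = fr$a + fr$c,
                     statistic = fr$odds_ratio, p_value = fr$p_value,
                     stringsAsFactors = FALSE)
      }
    }
    if (length(rows))
      write_tsv_sorted(do.call(rbind, rows), file.path(outdir, "tests.tsv"),
                       key = NULL, sort = FALSE)
    .log_line(logcon, "[stats] ", length(rows), " test(s) written")
  }

  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        c("run.log", "manifest.json")))
  manifest$files <- as.list(tools::md5sum(file.path(outdir, files)))
  names(manifest$files) <- files
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t_start,
                                              units = "secs"))
  manifest$timestamp <- format(t_start, "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

.config_echo <- function(config) {
  cfg <- config
  if (!is.null(cfg$synthetic)) {
    s <- cfg$synthetic; class(s) <- NULL
    cfg$synthetic <- s
  }
  cfg
}
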