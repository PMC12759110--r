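#' Construct a set of gene models
#'
#' A `gene_models` object is a data frame with one row per transcription
#' unit, carrying strand, 0-based half-open coordinates, an exon list-column
#' and a biotype. It is the coordinate anchor for every window, profile and
#' density computation in the package.
#'
#' Coordinates follow the BED convention throughout: 0-based, half-open
#' `[start, end)`. The TSS of a `+` strand gene is `start`; the TSS of a
#' `-` strand gene is `end` (the first transcribed base is `end - 1`).
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"` per gene.
#' @param start,end integer-valued gene span, `start < end`, 0-based half-open.
#' @param exons list of two-column matrices (`start`, `end` pairs), one per
#'   gene; must be sorted, non-overlapping and contained in `[start, end)`.
#'   Defaults to one exon spanning the whole gene.
#' @param biotype gene biotype (e.g. `"protein_coding"`); `NA` when unknown.
#' @return A data frame of class `gene_models`.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end,
                        exons = NULL, biotype = NA_character_) {
  n <- length(gene_id)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(strand) == 1) strand <- rep(strand, n)
  stopifnot(length(chrom) == n, length(strand) == n,
            length(start) == n, length(end) == n)
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  start <- as.numeric(start); end <- as.numeric(end)
  bad <- which(end <= start)
  if (length(bad))
    stop("gene end <= start for: ", paste(gene_id[bad], collapse = ", "))
  if (is.null(exons))
    exons <- mapply(function(s, e) cbind(start = s, end = e),
                    start, end, SIMPLIFY = FALSE)
  stopifnot(length(exons) == n)
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    if (!is.matrix(ex) || ncol(ex) != 2 || nrow(ex) < 1)
      stop("exons for ", gene_id[i], " must be a matrix with 2 columns")
    if (any(ex[, 2] <= ex[, 1]))
      stop("empty exon in ", gene_id[i])
    if (is.unsorted(ex[, 1]) || (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2])))
      stop("exons for ", gene_id[i], " must be sorted and non-overlapping")
    if (ex[1, 1] < start[i] || ex[nrow(ex), 2] > end[i])
      stop("exon outside gene span for ", gene_id[i])
    colnames(ex) <- c("start", "end")
    exons[[i]] <- ex
  }
  out <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    strand = as.character(strand),
                    start = start, end = end,
                    biotype = rep_len(as.character(biotype), n),
                    stringsAsFactors = FALSE)
  out$exons <- exons
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Gene lengths in base pairs
#' @param genes a `gene_models` object.
#' @return numeric vector, `end - start` per gene.
#' @export
gene_length <- function(genes) genes$end - genes$start

#' Total exonic length per gene
#' @param genes a `gene_models` object.
#' @export
exon_length <- function(genes)
  vapply(genes$exons, function(ex) sum(ex[, 2] - ex[, 1]), numeric(1))

#' Transcription start / end sites (strand aware)
#'
#' For a `+` strand gene the TSS is `start` and the TES is `end`; for a
#' `-` strand gene the TSS is `end` and the TES is `start`.
#' @param genes a `gene_models` object.
#' @export
tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end)

#' @rdname tss
#' @export
tes <- function(genes) ifelse(genes$strand == "+", genes$end, genes$start)

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  NextMethod()
}

# ---------------------------------------------------------------------------
# Gene model readers / writers

#' Read gene models from BED12 or GTF
#'
#' Dialect is auto-detected from the file extension (`.bed` vs `.gtf`/`.gff`)
#' and, failing that, from the first data line (9 tab fields with an
#' attribute column ending in `;`-separated `key "value"` pairs means GTF).
#' GTF coordinates (1-based, closed) are converted to the package's 0-based
#' half-open convention on read; exons are assembled per `gene_id` in
#' ascending coordinate order regardless of file order.
#'
#' @param path file path.
#' @param biotype_filter optional biotype (e.g. `"protein_coding"`); only
#'   matching gene models are returned.
#' @param format `"auto"`, `"bed12"` or `"gtf"`.
#' @return a `gene_models` object.
#' @export
read_gene_models <- function(path, biotype_filter = NULL,
                             format = c("auto", "bed12", "gtf")) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff", "gff2")) "gtf"
              else if (ext %in% c("bed", "bed12")) "bed12"
              else {
      first <- readLines(path, n = 50)
      first <- first[!grepl("^(#|track|browser)", first) & nzchar(first)]
      if (!length(first)) stop("cannot detect format of empty file: ", path)
      f <- strsplit(first[1], "\t", fixed = TRUE)[[1]]
      if (length(f) == 9 && grepl("gene_id", f[9])) "gtf" else "bed12"
    }
  }
  models <- switch(format,
                   bed12 = .read_bed12(path),
                   gtf = .read_gtf(path))
  if (!is.null(biotype_filter))
    models <- models[!is.na(models$biotype) & models$biotype == biotype_filter, ]
  models
}

.read_bed12 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(gene_models(character(), character(), character(),
                       numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("malformed BED line ", lineno[which(nf < 6)[1]],
         ": fewer than 6 fields")
  get <- function(i) vapply(fields, `[`, character(1), i)
  chrom <- get(1)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  name <- get(4)
  strand <- get(6)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], ": non-numeric coordinate")
  bad <- which(end <= start)
  if (length(bad))
    stop("invalid coordinates (end <= start) at line ", lineno[bad[1]])
  exons <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) >= 12) {
      sizes <- as.numeric(strsplit(f[11], ",", fixed = TRUE)[[1]])
      offs <- as.numeric(strsplit(f[12], ",", fixed = TRUE)[[1]])
      if (anyNA(sizes) || anyNA(offs) || length(sizes) != length(offs))
        stop("malformed BED block fields at line ", lineno[i])
      exons[[i]] <- cbind(start = start[i] + offs,
                          end = start[i] + offs + sizes)
    } else {
      exons[[i]] <- cbind(start = start[i], end = end[i])
    }
  }
  gene_models(name, chrom, strand, start, end, exons = exons)
}

.read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(gene_models(character(), character(), character(),
                       numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9))
    stop("malformed GTF line ", lineno[which(nf != 9)[1]],
         ": expected 9 tab-separated fields")
  get <- function(i) vapply(fields, `[`, character(1), i)
  feat <- get(3)
  use <- feat == "exon"
  if (!any(use)) stop("no exon features in GTF file: ", path)
  attr_field <- get(9)[use]
  grab <- function(key) {
    m <- regmatches(attr_field,
                    regexpr(paste0(key, '\\s+"[^"]*"'), attr_field))
    out <- rep(NA_character_, length(attr_field))
    hit <- grepl(paste0(key, '\\s+"'), attr_field)
    out[hit] <- sub(paste0('.*', key, '\\s+"([^"]*)".*'), "\\1",
                    attr_field[hit])
    out
  }
  gid <- grab("gene_id")
  if (anyNA(gid))
    stop("malformed GTF line ", lineno[use][which(is.na(gid))[1]],
         ": missing gene_id attribute")
  bio <- grab("gene_biotype")
  if (all(is.na(bio))) bio <- grab("gene_type")
  chrom <- get(1)[use]
  # GTF is 1-based closed; convert to 0-based half-open
  start1 <- suppressWarnings(as.numeric(get(4)[use])) - 1
  end1 <- suppressWarnings(as.numeric(get(5)[use]))
  strand <- get(7)[use]
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad))
    stop("malformed GTF line ", lineno[use][bad[1]], ": non-numeric coordinate")
  bad <- which(end1 <= start1)
  if (length(bad))
    stop("invalid coordinates (end <= start) at line ", lineno[use][bad[1]])
  ord <- order(gid, start1)
  gid <- gid[ord]; chrom <- chrom[ord]; start1 <- start1[ord]
  end1 <- end1[ord]; strand <- strand[ord]; bio <- bio[ord]
  idx <- split(seq_along(gid), gid)
  ids <- names(idx)
  exons <- lapply(idx, function(i) cbind(start = start1[i], end = end1[i]))
  first <- vapply(idx, `[`, integer(1), 1)
  gene_models(ids,
              chrom = chrom[first],
              strand = strand[first],
              start = vapply(idx, function(i) min(start1[i]), numeric(1)),
              end = vapply(idx, function(i) max(end1[i]), numeric(1)),
              exons = exons,
              biotype = bio[first])
}

#' Write gene models as BED12
#'
#' Rows are emitted sorted by `(chrom, start, gene_id)` so output is
#' byte-deterministic. Biotype is not representable in BED12 and is dropped.
#'
#' @param genes a `gene_models` object.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  ord <- order(genes$chrom, genes$start, genes$gene_id)
  genes <- genes[ord, ]
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    sizes <- paste0(paste(format(ex[, 2] - ex[, 1], scientific = FALSE,
                                 trim = TRUE), collapse = ","), ",")
    offs <- paste0(paste(format(ex[, 1] - genes$start[i], scientific = FALSE,
                                trim = TRUE), collapse = ","), ",")
    paste(genes$chrom[i],
          format(genes$start[i], scientific = FALSE, trim = TRUE),
          format(genes$end[i], scientific = FALSE, trim = TRUE),
          genes$gene_id[i], 0, genes$strand[i],
          format(genes$start[i], scientific = FALSE, trim = TRUE),
          format(genes$end[i], scientific = FALSE, trim = TRUE),
          "0", nrow(ex), sizes, offs, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Coverage tracks

#' Construct a coverage track
#'
#' Holds non-negative signal over genomic intervals together with a library
#' size normalizer. Overlapping input intervals are merged by summation so
#' the stored representation is sorted and disjoint per chromosome; a
#' cumulative integral is precomputed so that the exact signal in any
#' (possibly fractional) window is an O(log n) lookup.
#'
#' @param chrom,start,end,value parallel vectors describing intervals
#'   (0-based half-open) and their per-base signal value.
#' @param library_size total tag count used for normalization; defaults to
#'   the total signal `sum(value * (end - start))`.
#' @param label free-text label (mark/assay + condition).
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(chrom = character(), start = numeric(),
                           end = numeric(), value = numeric(),
                           library_size = NULL, label = "") {
  if (length(start) > 1) {
    if (length(chrom) == 1) chrom <- rep(chrom, length(start))
    if (length(value) == 1) value <- rep(value, length(start))
  }
  stopifnot(length(chrom) == length(start),
            length(start) == length(end),
            length(end) == length(value))
  if (any(value < 0)) stop("coverage values must be non-negative")
  if (any(end <= start)) stop("coverage intervals must have end > start")
  chroms <- list()
  for (ch in sort(unique(chrom))) {
    i <- chrom == ch
    chroms[[ch]] <- .merge_segments(start[i], end[i], value[i])
  }
  total <- sum(vapply(chroms, function(s) s$cum[length(s$cum)], numeric(1)), 0)
  if (is.null(library_size)) library_size <- total
  if (library_size < 0) stop("library_size must be >= 0")
  structure(list(chroms = chroms, library_size = library_size,
                 total_signal = total, label = label),
            class = "coverage_track")
}

# Sweep-line merge: overlapping intervals sum, producing disjoint segments
# with a cumulative integral (cum[i] = signal strictly before segment i).
.merge_segments <- function(start, end, value) {
  pos <- c(start, end)
  delta <- c(value, -value)
  o <- order(pos)
  pos <- pos[o]; delta <- delta[o]
  upos <- unique(pos)
  lev <- cumsum(rowsum(delta, group = match(pos, upos))[, 1])
  seg_start <- upos[-length(upos)]
  seg_end <- upos[-1]
  seg_val <- pmax(lev[-length(lev)], 0)  # clamp float residue from the sweep
  keep <- seg_val > 0
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
  seg_val <- seg_val[keep]
  list(start = seg_start, end = seg_end, value = seg_val,
       cum = c(0, cumsum(seg_val * (seg_end - seg_start))))
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> '%s': %d segment(s) on %d chromosome(s), total signal %.4g, library size %.4g\n",
    x$label, sum(vapply(x$chroms, function(s) length(s$start), integer(1)), 0),
    length(x$chroms), x$total_signal, x$library_size))
  invisible(x)
}

#' Cumulative signal up to arbitrary positions
#'
#' Returns S(x) = total signal in `[0, x)` on one chromosome. Positions may
#' be fractional; a base contributes proportionally to the overlapped part,
#' which is what makes fractional metagene bins exact.
#'
#' @param track a `coverage_track`.
#' @param chrom chromosome name (scalar).
#' @param pos numeric positions.
#' @return numeric vector of cumulative signal values.
#' @export
track_cumsignal <- function(track, chrom, pos) {
  seg <- track$chroms[[chrom]]
  if (is.null(seg) || !length(seg$start)) return(numeric(length(pos)))
  i <- findInterval(pos, seg$start)
  out <- numeric(length(pos))
  hit <- i > 0
  ih <- i[hit]
  out[hit] <- seg$cum[ih] +
    seg$value[ih] * pmin(pmax(pos[hit] - seg$start[ih], 0),
                         seg$end[ih] - seg$start[ih])
  out
}

#' Exact signal in windows
#'
#' @param track a `coverage_track`.
#' @param chrom chromosome per window (vector ok).
#' @param start,end window bounds (clipped at 0).
#' @return numeric vector of total signal per window.
#' @export
track_window_sum <- function(track, chrom, start, end) {
  start <- pmax(start, 0); end <- pmax(end, 0)
  out <- numeric(length(start))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    out[i] <- track_cumsignal(track, ch, end[i]) -
      track_cumsignal(track, ch, start[i])
  }
  out
}

#' Read a bedGraph coverage file
#'
#' Overlapping intervals are summed (tolerant of replicate-pooled tracks).
#' An empty file yields an empty track with library size 0.
#'
#' @inheritParams coverage_track
#' @param path 4-column bedGraph file; `track`/comment lines are skipped.
#' @export
read_coverage <- function(path, library_size = NULL, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(coverage_track(library_size = if (is.null(library_size)) 0
                                         else library_size,
                          label = label))
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) != 4)
    stop("bedGraph must have 4 columns, found ", ncol(dt), " in ", path)
  val <- as.numeric(dt[[4]])
  if (anyNA(val))
    stop("non-numeric value at line ", lineno[which(is.na(val))[1]])
  if (any(val < 0))
    stop("negative coverage value at line ", lineno[which(val < 0)[1]])
  coverage_track(dt[[1]], as.numeric(dt[[2]]), as.numeric(dt[[3]]), val,
                 library_size = library_size, label = label)
}

#' Write a coverage track as bedGraph
#'
#' Segments are written sorted by `(chrom, start)`; zero-signal gaps are
#' omitted. Values are formatted with full precision so write/read
#' round-trips reproduce identical window queries.
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @export
write_coverage <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in sort(names(track$chroms))) {
    seg <- track$chroms[[ch]]
    if (!length(seg$start)) next
    writeLines(paste(ch,
                     format(seg$start, scientific = FALSE, trim = TRUE),
                     format(seg$end, scientific = FALSE, trim = TRUE),
                     format(seg$value, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Windows

#' Define a genomic window relative to an anchor
#'
#' Windows are strand-aware: offsets are in transcribed orientation, so
#' negative offsets mean upstream of the anchor on either strand. Anchor
#' `"absolute"` treats `rel_start`/`rel_end` as absolute coordinates.
#'
#' @param anchor `"TSS"`, `"TES"` or `"absolute"`.
#' @param rel_start,rel_end signed offsets in bp, `rel_start < rel_end`.
#' @export
genomic_window <- function(anchor = c("TSS", "TES", "absolute"),
                           rel_start, rel_end) {
  anchor <- match.arg(anchor)
  if (rel_start >= rel_end) stop("rel_start must be < rel_end")
  structure(list(anchor = anchor, rel_start = rel_start, rel_end = rel_end),
            class = "genomic_window")
}

#' @export
print.genomic_window <- function(x, ...) {
  cat(sprintf("<genomic_window> %s%+d..%+d\n", x$anchor,
              x$rel_start, x$rel_end))
  invisible(x)
}

#' Resolve a relative window to absolute coordinates
#'
#' For a `+` strand gene, `TSS + rel_start .. TSS + rel_end`; for a `-`
#' strand gene the window is mirrored: `TSS - rel_end .. TSS - rel_start`.
#' Results are clipped at position 0 (windows may shrink at chromosome
#' edges).
#'
#' @param genes a `gene_models` object.
#' @param window a `genomic_window`.
#' @return data frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
resolve_window <- function(genes, window) {
  stopifnot(inherits(window, "genomic_window"))
  anchor_pos <- switch(window$anchor,
                       TSS = tss(genes),
                       TES = tes(genes),
                       absolute = rep(0, nrow(genes)))
  plus <- genes$strand == "+" | window$anchor == "absolute"
  s <- ifelse(plus, anchor_pos + window$rel_start,
              anchor_pos - window$rel_end)
  e <- ifelse(plus, anchor_pos + window$rel_end,
              anchor_pos - window$rel_start)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(s, 0), end = pmax(e, 0),
             stringsAsFactors = FALSE)
}
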