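# density computations against per-base oracles, profile shapes, and
# normalization invariants

test_that("window_density matches the worked promoter example", {
  tr <- coverage_track("chr1", 9700, 10200, 4.0, library_size = 1e7)
  g <- gene_models("g1", "chr1", "+", 10000, 30000)
  wd <- window_density(tr, g, genomic_window("TSS", -300, 200))
  expect_equal(wd$raw_tags, 2000)        # 4 tags/base * 500 bp
  expect_equal(wd$norm_density, 4000)    # 2000 / 0.5 kb / (1e7/1e7)

  # mirrored minus-strand construction gives identical raw tags
  trm <- coverage_track("chr1", 100000 - 10200, 100000 - 9700, 4.0,
                        library_size = 1e7)
  gm <- gene_models("g1", "chr1", "-", 70000, 90000)
  wdm <- window_density(trm, gm, genomic_window("TSS", -300, 200))
  expect_equal(wdm$raw_tags, wd$raw_tags)

  # empty track
  wd0 <- window_density(coverage_track(), g, genomic_window("TSS", -300, 200))
  expect_equal(wd0$raw_tags, 0)
  expect_equal(wd0$norm_density, 0)
})

test_that("window and body densities equal the per-base oracle on random tracks", {
  set.seed(31)
  for (k in 1:40) {
    iv <- random_intervals(sample(1:40, 1))
    tr <- track_from_intervals(iv)
    s <- sample.int(4000, 1) + 500
    e <- s + sample.int(1500, 1) + 120
    g <- gene_models("g", "chr1", sample(c("+", "-"), 1), s, e)
    w <- genomic_window("TSS", -sample.int(400, 1), sample.int(400, 1))
    res <- resolve_window(g, w)
    expect_identical(window_density(tr, g, w)$raw_tags,
                     oracle_window_sum(iv, "chr1", res$start, res$end))
    bd <- gene_body_density(tr, g, promoter_exclusion_bp = 100)
    bs <- if (g$strand == "+") s + 100 else s
    be <- if (g$strand == "+") e else e - 100
    expect_identical(bd$raw_tags, oracle_window_sum(iv, "chr1", bs, be))
  }
})

test_that("gene_body_density honours promoter exclusion and guards", {
  g <- gene_models("g", "chr1", "+", 1000, 3000)
  # promoter-peaked construction: high signal only near the TSS
  tr <- coverage_track(c("chr1", "chr1"), c(1000, 1500), c(1500, 3000),
                       c(10, 1))
  d0 <- gene_body_density(tr, g, 0)$norm_density
  d500 <- gene_body_density(tr, g, 500)$norm_density
  expect_lt(d500, d0)
  expect_error(gene_body_density(tr, g, 2000), "g")
  expect_equal(gene_body_density(coverage_track(), g)$norm_density, 0)
})

test_that("tss_profile is flat on uniform signal and peaks at the TSS", {
  set.seed(12)
  n <- 30
  s <- 20000 + (0:(n - 1)) * 9000
  g <- gene_models(sprintf("g%02d", 1:n), "chr1",
                   sample(c("+", "-"), n, TRUE), s, s + 5000)
  tr <- coverage_track("chr1", 0, 4e5, 3)
  prof <- tss_profile(tr, g, flank_bp = 2000, bin_bp = 100)
  expect_equal(nrow(prof), 40)
  expect_true(all(abs(prof$mean_density - prof$mean_density[1]) < 1e-9))
  expect_true(all(prof$n_genes == n))

  # promoter-peaked: one high interval right at each TSS
  t0 <- tss(g)
  tr2 <- coverage_track(rep("chr1", n), t0 - 50, t0 + 50, 50)
  prof2 <- tss_profile(tr2, g, flank_bp = 2000, bin_bp = 100)
  peak_bins <- which(prof2$mean_density == max(prof2$mean_density))
  expect_true(all(prof2$rel_start[peak_bins] %in% c(-100, 0)))
  expect_error(tss_profile(tr, g[0, ]), "empty")
})

test_that("profiles are invariant under strand flip + coordinate mirror", {
  set.seed(77)
  L <- 6e5
  n <- 15
  s <- 30000 + (0:(n - 1)) * 30000
  len <- sample(3000:8000, n, TRUE)
  g <- gene_models(sprintf("g%02d", 1:n), "chr1", "+", s, s + len)
  iv <- random_intervals(150, max_pos = L - 500)
  tr <- track_from_intervals(iv)
  # mirror the whole system
  gm <- gene_models(g$gene_id, "chr1", "-", L - (s + len), L - s)
  ivm <- data.frame(chrom = "chr1", start = L - iv$end, end = L - iv$start,
                    value = iv$value)
  trm <- track_from_intervals(ivm)
  p1 <- tss_profile(tr, g, 2000, 100)
  p2 <- tss_profile(trm, gm, 2000, 100)
  expect_equal(p2$mean_density, p1$mean_density)
  m1 <- metagene_profile(tr, g, n_body_bins = 50, flank_bp = 1000,
                         n_flank_bins = 10)
  m2 <- metagene_profile(trm, gm, n_body_bins = 50, flank_bp = 1000,
                         n_flank_bins = 10)
  expect_equal(m2$bin_means, m1$bin_means)
})

test_that("metagene profile geometry and degenerate cases behave", {
  set.seed(3)
  n <- 12
  s <- 50000 + (0:(n - 1)) * 40000
  len <- sample(4000:20000, n, TRUE)
  g <- gene_models(sprintf("g%02d", 1:n), "chr1",
                   sample(c("+", "-"), n, TRUE), s, s + len)
  # constant coverage over bodies only, zero flanks
  tr <- coverage_track(rep("chr1", n), g$start, g$end, 5)
  mp <- metagene_profile(tr, g, n_body_bins = 40, flank_bp = 2000,
                         n_flank_bins = 10)
  body <- mp$bin_means[mp$bin_region == "body"]
  flank <- mp$bin_means[mp$bin_region != "body"]
  expect_equal(length(mp$bin_means), 60)
  expect_true(all(abs(body / body[1] - 1) < 1e-9))
  expect_true(all(flank == 0))
  # n_body_bins = 1 equals the across-gene mean of gene-body densities
  mp1 <- metagene_profile(tr, g, n_body_bins = 1, flank_bp = 1000,
                          n_flank_bins = 2)
  expect_equal(mp1$bin_means[3],
               mean(gene_body_density(tr, g)$norm_density))
  # short genes excluded with a count
  gshort <- gene_models("tiny", "chr1", "+", 10, 40)
  expect_message(
    mp2 <- metagene_profile(tr, rbind_genes(g, gshort), n_body_bins = 40,
                            flank_bp = 1000, n_flank_bins = 2),
    "excluded")
  expect_equal(mp2$n_excluded, 1)
  expect_equal(mp2$n_genes, n)
  expect_error(metagene_profile(tr, gshort, n_body_bins = 40), "none left")
})

test_that("profile_matrix sorts by window density with gene_id tiebreak", {
  g <- gene_models(c("b", "a", "c"), "chr1", "+",
                   c(10000, 30000, 50000), c(20000, 40000, 60000))
  # sort-window densities: b = 9, a = 5, c = 5 (tie between a and c)
  tr <- coverage_track(rep("chr1", 3), c(9500, 29500, 49500),
                       c(10200, 30200, 50200), c(9, 5, 5))
  pm <- profile_matrix(tr, g, genomic_window("TSS", -3000, 3000),
                       bin_bp = 50,
                       sort_window = genomic_window("TSS", -500, 200))
  expect_equal(ncol(pm$matrix), 120)   # +/- 3 kb in 50 bp bins
  expect_equal(rownames(pm$matrix), c("b", "a", "c"))
  # unsorted keeps input order
  pm0 <- profile_matrix(tr, g, genomic_window("TSS", -3000, 3000), 50)
  expect_equal(rownames(pm0$matrix), c("b", "a", "c"))
})

test_that("densities are linear in signal and inverse in library size", {
  set.seed(8)
  iv <- random_intervals(80)
  tr1 <- track_from_intervals(iv)
  iv3 <- iv; iv3$value <- iv$value * 3
  tr3 <- track_from_intervals(iv3, library_size = tr1$library_size)
  g <- gene_models("g", "chr1", "+", 1000, 4000)
  w <- genomic_window("TSS", -200, 400)
  expect_equal(window_density(tr3, g, w)$norm_density,
               3 * window_density(tr1, g, w)$norm_density)
  tr2 <- track_from_intervals(iv, library_size = 2 * tr1$library_size)
  expect_equal(window_density(tr2, g, w)$norm_density,
               window_density(tr1, g, w)$norm_density / 2)
})
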