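# the generator: determinism, planted lengths/effects, noise models

test_that("generation is deterministic and child-seeded per output", {
  cfg <- synthetic_config(n_genes = 80, depth = 5e4, expr_depth = 5e4,
                          seed = 3)
  g1 <- generate_genes(cfg)
  g2 <- generate_genes(cfg)
  expect_identical(g1, g2)
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_gene_models(g1$genes, f1)
  write_gene_models(g2$genes, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a track depends only on (seed, mark, condition), not on other tracks
  t_a <- generate_mark_track(g1$genes, g1$truth, cfg, "H3K79me3", "EPQ")
  generate_mark_track(g1$genes, g1$truth, cfg, "H4R3me2s", "SEN")
  t_b <- generate_mark_track(g1$genes, g1$truth, cfg, "H3K79me3", "EPQ")
  expect_identical(t_a, t_b)
  expect_error(generate_mark_track(g1$genes, g1$truth, cfg, "H3K4me3",
                                   "EPQ"), "H3K4me3")
})

test_that("genes are placed non-overlapping with >= 10 kb gaps", {
  cfg <- synthetic_config(n_genes = 120, seed = 5)
  g <- generate_genes(cfg)$genes
  expect_true(all(g$end > g$start))
  gaps <- g$start[-1] - g$end[-nrow(g)]
  expect_true(all(gaps >= cfg$min_gap))
  expect_true(all(table(generate_genes(cfg)$truth$label)[
    c("GAINED", "LOST")] == c(12, 12)))
})

test_that("gained_length_bias shifts the GAINED length distribution", {
  cfg <- synthetic_config(n_genes = 2000, gained_length_bias = 3, seed = 21)
  g <- generate_genes(cfg)
  len <- gene_length(g$genes)
  expect_gt(median(len[g$truth$label == "GAINED"]),
            median(len[g$truth$label == "UNCHANGED"]))
  # null bias: Mann-Whitney p-values roughly uniform over replicate seeds
  ps <- vapply(1:20, function(s) {
    gg <- generate_genes(synthetic_config(n_genes = 300,
                                          gained_length_bias = 1,
                                          seed = s))
    l <- gene_length(gg$genes)
    mann_whitney_u(l[gg$truth$label == "GAINED"],
                   l[gg$truth$label == "UNCHANGED"])$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("expression counts recover planted effects", {
  cfg0 <- synthetic_config(n_genes = 400, expr_effect = 0,
                           expr_depth = 1e6, seed = 9)
  g0 <- generate_genes(cfg0)
  ct0 <- generate_expression_counts(g0$genes, g0$truth, cfg0)
  fc0 <- fold_change_table(ct0$rna, ct0$gro,
                           libsize = rep(cfg0$expr_depth, 2))
  expect_lt(abs(mean(fc0$combined)), 0.05)

  cfg2 <- synthetic_config(n_genes = 400, expr_effect = 2,
                           expr_depth = 1e6, seed = 9)
  g2 <- generate_genes(cfg2)
  ct2 <- generate_expression_counts(g2$genes, g2$truth, cfg2)
  fc2 <- fold_change_table(ct2$rna, ct2$gro,
                           libsize = rep(cfg2$expr_depth, 2))
  gained <- g2$truth$label == "GAINED"
  expect_lt(abs(mean(fc2$combined[gained]) - 2), 0.15)
  # RNA and GRO concordant in sign for planted genes
  expect_true(all(sign(fc2$log2fc_rna[gained]) ==
                  sign(fc2$log2fc_gro[gained])))
})

test_that("negative binomial dispersion widens observed fold changes", {
  base <- list(n_genes = 400, expr_effect = 0, expr_depth = 2e5, seed = 13)
  v <- vapply(c(0.05, 0.5), function(d) {
    cfg <- do.call(synthetic_config,
                   c(base, list(noise = "negative_binomial",
                                nb_dispersion = d)))
    g <- generate_genes(cfg)
    ct <- generate_expression_counts(g$genes, g$truth, cfg)
    var(fold_change_table(ct$rna)$log2fc_rna)
  }, numeric(1))
  expect_gt(v[2], v[1])
})

test_that("mark tracks realize the configured shapes", {
  shapes <- list(M = list(
    EPQ = mark_shape(0, 100, body_level = 2),
    SEN = mark_shape(0, 100, body_level = 2)))
  cfg <- synthetic_config(n_genes = 40, mark_shapes = shapes,
                          coupled_mark = "none", depth = 2e5, seed = 17)
  g <- generate_genes(cfg)
  tr <- generate_mark_track(g$genes, g$truth, cfg, "M", "EPQ")
  # amplitude 0: signal confined to gene bodies (up to bin discretization)
  gaps_mid <- (g$genes$end[-nrow(g$genes)] + g$genes$start[-1]) / 2
  expect_true(all(track_window_sum(tr, "chrS", gaps_mid - 2000,
                                   gaps_mid + 2000) == 0))
  # uniform over bodies: per-gene density ~ constant
  bd <- gene_body_density(tr, g$genes)$norm_density
  expect_lt(stats::sd(bd) / mean(bd), 0.2)
  # total tags within 3 sd of configured depth (Poisson)
  expect_lt(abs(tr$total_signal - cfg$depth), 3 * sqrt(cfg$depth))
})

test_that("promoter mark loss is planted on GAINED genes only", {
  sim <- small_sim()
  mc <- mark_change(sim$tracks$H4R3me2s_EPQ, sim$tracks$H4R3me2s_SEN,
                    sim$genes, genomic_window("TSS", -300, 200))
  lfc <- split(mc$log2fc_mark, sim$truth$label)
  expect_lt(median(lfc$GAINED), -3)
  expect_lt(abs(median(lfc$UNCHANGED)), 0.5)
  expect_lt(abs(median(lfc$LOST)), 0.5)
})

test_that("spreading appears in condition 2 only", {
  sim <- small_sim()
  m1 <- metagene_profile(sim$tracks$H3K79me3_EPQ, sim$genes)
  m2 <- metagene_profile(sim$tracks$H3K79me3_SEN, sim$genes)
  b1 <- m1$bin_means[m1$bin_region == "body"]
  b2 <- m2$bin_means[m2$bin_region == "body"]
  expect_lte(which.max(b1), 10)          # 5'-peaked in condition 1
  expect_gt(mean(b2[21:100]), mean(b1[21:100]))  # elevated body beyond bin 20
})

test_that("simulate_dataset writes a deterministic file set", {
  cfg <- synthetic_config(n_genes = 30, depth = 2e4, expr_depth = 2e4,
                          seed = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, outdir = d1)
  simulate_dataset(cfg, outdir = d2)
  files <- list.files(d1)
  expect_setequal(files, c("genes.bed", "rna_counts.tsv", "gro_counts.tsv",
                           "ground_truth.tsv", "config.yaml",
                           "H3K79me3_EPQ.bedGraph", "H3K79me3_SEN.bedGraph",
                           "H4R3me2s_EPQ.bedGraph", "H4R3me2s_SEN.bedGraph"))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})
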