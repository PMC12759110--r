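# fold changes, regulation calls, length strata, pausing indices

test_that("log2_fold_change follows the pseudocount formula", {
  # equal normalized counts
  expect_equal(log2_fold_change(10, 10, 100, 100)$log2fc, 0)
  # 4x normalized ratio, counts >> pseudocount
  lfc <- log2_fold_change(1000, 4000, 1e6, 1e6)$log2fc
  expect_lt(abs(lfc - 2), 0.005)
  # double zeros are exactly 0 with equal library sizes
  expect_equal(log2_fold_change(0, 0, 5e5, 5e5)$log2fc, 0)
  # library-size correction
  expect_equal(log2_fold_change(100, 100, 1e6, 2e6, pseudocount = 0)$log2fc,
               -1)
})

test_that("combined fold change averages RNA and GRO when both exist", {
  rna <- data.frame(gene_id = c("a", "b"), c1 = c(100, 100),
                    c2 = c(400, 100))
  gro <- data.frame(gene_id = c("a", "b"), c1 = c(100, 100),
                    c2 = c(100, 100))
  fc <- fold_change_table(rna, gro, libsize = c(1000, 1000))
  expect_equal(fc$combined[1], (fc$log2fc_rna[1] + fc$log2fc_gro[1]) / 2)
  fc_rna_only <- fold_change_table(rna, libsize = c(1000, 1000))
  expect_equal(fc_rna_only$combined, fc_rna_only$log2fc_rna)
})

test_that("classify_regulation applies thresholds and concordance", {
  fc <- data.frame(
    gene_id = c("up", "disc", "down", "flat", "off"),
    log2fc_rna = c(2, 2, -2, 0.2, 3),
    log2fc_gro = c(1, -0.3, -1.5, NA, 3),
    stringsAsFactors = FALSE)
  fc$combined <- ifelse(is.na(fc$log2fc_gro), fc$log2fc_rna,
                        (fc$log2fc_rna + fc$log2fc_gro) / 2)
  calls <- classify_regulation(fc, expressed = c("up", "disc", "down",
                                                 "flat"))
  got <- setNames(calls$label, calls$gene_id)
  expect_equal(got[["up"]], "S_GAINED")
  expect_equal(got[["disc"]], "UNCHANGED")   # discordant signs
  expect_equal(got[["down"]], "S_LOST")
  expect_equal(got[["flat"]], "UNCHANGED")
  expect_equal(got[["off"]], "NOT_EXPRESSED")
  # without concordance requirement the discordant gene is called
  calls2 <- classify_regulation(fc, expressed = fc$gene_id,
                                require_concordance = FALSE)
  expect_equal(calls2$label[calls2$gene_id == "disc"], "UNCHANGED")
  # combined = 0.85 < 1, still unchanged; push it over
  fc$combined[fc$gene_id == "disc"] <- 1.2
  calls3 <- classify_regulation(fc, expressed = fc$gene_id,
                                require_concordance = FALSE)
  expect_equal(calls3$label[calls3$gene_id == "disc"], "S_GAINED")
  expect_error(classify_regulation(fc, fc$gene_id, up_thresh = -1), "thresh")
})

test_that("classification is an exhaustive partition on random inputs", {
  set.seed(19)
  for (k in 1:10) {
    n <- 200
    fc <- data.frame(gene_id = as.character(1:n),
                     log2fc_rna = rnorm(n, 0, 2),
                     log2fc_gro = ifelse(runif(n) < 0.3, NA, rnorm(n, 0, 2)))
    fc$combined <- ifelse(is.na(fc$log2fc_gro), fc$log2fc_rna,
                          (fc$log2fc_rna + fc$log2fc_gro) / 2)
    calls <- classify_regulation(fc, expressed = sample(fc$gene_id, 150))
    expect_equal(nrow(calls), n)
    expect_true(all(calls$label %in% c("S_GAINED", "S_LOST", "UNCHANGED",
                                       "NOT_EXPRESSED")))
  }
})

test_that("length_stratify uses half-open bins", {
  g <- gene_models(c("a", "b", "c", "d"), "chr1", "+",
                   c(0, 0, 0, 0), c(9999, 10000, 30000, 150000))
  ls <- length_stratify(g)
  expect_equal(as.character(ls$bin),
               c("[0,10000)", "[10000,30000)", "[30000,100000)",
                 "[100000,Inf)"))
  # empty edges: a single bin holds everything
  ls0 <- length_stratify(g, edges = numeric())
  expect_equal(length(unique(ls0$bin)), 1)
  expect_error(length_stratify(g, edges = c(30000, 10000)), "increasing")
})

test_that("pausing index is 1 on uniform coverage and scale-invariant", {
  set.seed(23)
  n <- 15
  s <- 10000 + (0:(n - 1)) * 30000
  len <- sample(2000:15000, n, TRUE)
  g <- gene_models(sprintf("g%02d", 1:n), "chr1",
                   sample(c("+", "-"), n, TRUE), s, s + len)
  tr <- coverage_track("chr1", 0, 6e5, 2)
  rec <- pausing_index(tr, g)
  expect_true(all(rec$valid))
  expect_true(all(abs(rec$pi - 1) < 1e-9))
  tr5 <- coverage_track("chr1", 0, 6e5, 10)
  expect_equal(pausing_index(tr5, g)$pi, rec$pi)

  # promoter 10x body
  g1 <- gene_models("p10", "chr1", "+", 50000, 60000)
  trp <- coverage_track(c("chr1", "chr1"), c(49950, 50300),
                        c(50300, 60000), c(10, 1))
  expect_equal(pausing_index(trp, g1)$pi, 10)

  # zero body coverage -> invalid
  trz <- coverage_track("chr1", 49950, 50300, 4)
  recz <- pausing_index(trz, g1)
  expect_false(recz$valid)
  expect_equal(recz$reason, "zero_body_density")
  # too-short gene -> invalid record, not an error
  gs <- gene_models("tiny", "chr1", "+", 100, 450)
  recs <- pausing_index(tr, gs)
  expect_false(recs$valid)
  expect_equal(recs$reason, "too_short")
})

test_that("pi_curve is a monotone ecdf that reports invalid records", {
  rec <- data.frame(gene_id = as.character(1:6),
                    promoter_density = 1, body_density = 1,
                    pi = c(2, 2, 5, 1, NA, NA),
                    valid = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                    reason = "")
  cur <- pi_curve(rec)
  expect_equal(nrow(cur), 4)             # duplicates keep their own points
  expect_equal(cur$pi, c(1, 2, 2, 5))
  expect_true(all(diff(cur$cum_frac) >= 0))
  expect_equal(attr(cur, "n_invalid"), 2)
  expect_error(pi_curve(rec[rec$pi > 100 & !is.na(rec$pi), ]), "valid")

  # stochastic dominance shifts the curve right
  set.seed(4)
  a <- rec[1:4, ]; a$pi <- rlnorm(4, 2, 0.1)
  b <- rec[1:4, ]; b$pi <- rlnorm(4, 0, 0.1)
  expect_gt(min(pi_curve(a)$pi), max(pi_curve(b)$pi))
})

test_that("delta_pi is zero on identical tracks and -1 on halved promoters", {
  set.seed(29)
  n <- 10
  s <- 20000 + (0:(n - 1)) * 30000
  g <- gene_models(sprintf("g%02d", 1:n), "chr1", "+", s, s + 8000)
  t0 <- tss(g)
  mk <- function(pval) {
    coverage_track(rep("chr1", 2 * n), c(t0 - 50, t0 + 300),
                   c(t0 + 300, s + 8000), c(rep(pval, n), rep(2, n)))
  }
  ra <- pausing_index(mk(8), g)
  rb <- pausing_index(mk(4), g)
  expect_equal(delta_pi(ra, ra)$delta_log2_pi, rep(0, n))
  d <- delta_pi(ra, rb)
  expect_equal(d$delta_log2_pi, rep(-1, n))
  # exclusion bookkeeping: invalidate one gene in a only
  ra2 <- ra; ra2$valid[1] <- FALSE
  d2 <- delta_pi(ra2, rb)
  expect_false(g$gene_id[1] %in% d2$gene_id)
  expect_equal(attr(d2, "n_excluded"), 1)
  expect_error(delta_pi(ra[0, ], rb), "valid")
})

test_that("planted regulation is recovered on the small dataset", {
  sim <- small_sim()
  fc <- fold_change_table(sim$counts$rna, sim$counts$gro,
                          libsize = rep(sim$config$expr_depth, 2))
  calls <- classify_regulation(fc, expressed_genes(sim$counts$rna,
                                                   sim$genes))
  tab <- table(truth = sim$truth$label, call = calls$label)
  expect_gt(tab["GAINED", "S_GAINED"] / sum(tab["GAINED", ]), 0.8)
  expect_gt(tab["LOST", "S_LOST"] / sum(tab["LOST", ]), 0.8)
})
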