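paired_design <- function(donors, reps_per_bin = 1) {
  d <- rep(sprintf("d%d", seq_len(donors)), each = 2 * reps_per_bin)
  data.frame(sample_id = sprintf("s%d", seq_along(d)), donor = d,
             bin = rep(c("LOW", "HIGH"), donors * reps_per_bin))
}

test_that("size factors reproduce the hand-computed median-of-ratios", {
  m <- matrix(c(2, 6, 4, 12), nrow = 2)  # rows (2,4), (6,12)
  s <- size_factors(m)
  # geometric means (2.828, 8.485); per-column ratio medians by hand
  expect_equal(unname(s), c(0.70710678, 1.41421356), tolerance = 1e-7)

  # identical columns give unit factors; scaling a column scales its factor
  m2 <- matrix(rpois(200, 50) + 1L, ncol = 2)
  m2[, 2] <- m2[, 1]
  expect_equal(unname(size_factors(m2)), c(1, 1))
  m3 <- m2; m3[, 2] <- m3[, 2] * 5
  expect_equal(unname(size_factors(m3))[2], 5 * unname(size_factors(m3))[1])

  # rows containing a zero are excluded from the median
  m4 <- rbind(m, c(0, 1000))
  expect_equal(size_factors(m4), s)
  expect_error(size_factors(rbind(c(0, 1), c(1, 0))), "all-positive")
})

test_that("dispersion estimation recovers a known NB dispersion", {
  set.seed(101)
  cnt <- matrix(rnbinom(200 * 6, mu = 300, size = 1 / 0.1), 200,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6)))
  des <- paired_design(3)
  disp <- fit_dispersions(cnt, size_factors(cnt), des)
  med <- median(disp$table$alpha_final, na.rm = TRUE)
  expect_gte(med, 0.05)
  expect_lte(med, 0.2)
  # shrinkage keeps the final estimate between raw and trend in log space
  tab <- disp$table[disp$table$ok & !disp$table$at_floor, ]
  lo <- pmin(log(tab$alpha_raw), log(tab$alpha_trend)) - 1e-6
  hi <- pmax(log(tab$alpha_raw), log(tab$alpha_trend)) + 1e-6
  expect_true(all(log(tab$alpha_final) >= lo & log(tab$alpha_final) <= hi))
})

test_that("Poisson data drives dispersions to the floor", {
  set.seed(102)
  cnt <- matrix(rpois(200 * 6, 300), 200,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6)))
  des <- paired_design(3)
  disp <- fit_dispersions(cnt, size_factors(cnt), des)
  frac_floor <- mean(disp$table$alpha_final <= 1e-8 * 1.01, na.rm = TRUE)
  expect_gte(frac_floor, 0.9)

  # a guide with identical counts everywhere has no excess variance
  cnt2 <- rbind(cnt, flat = rep(250L, 6))
  disp2 <- fit_dispersions(cnt2, rep(1, 6), des)
  expect_lte(disp2$table$alpha_raw[nrow(cnt2)], 1e-8 * 1.01)

  # all-zero guides are flagged and excluded downstream
  cnt3 <- rbind(cnt, zero = rep(0L, 6))
  disp3 <- fit_dispersions(cnt3, rep(1, 6), des)
  expect_false(disp3$table$ok[nrow(cnt3)])
  res3 <- paired_nb_wald(cnt3, rep(1, 6), disp3, des)
  expect_true(is.na(res3$pvalue[nrow(cnt3)]))
})

test_that("the paired Wald test is exact in degenerate cases", {
  des <- paired_design(3)
  # counts equal across bins within each donor: null fit, beta = 0, p ~ 1
  cnt <- matrix(rep(c(100L, 100L, 220L, 220L, 87L, 87L), each = 5), 5,
                byrow = FALSE,
                dimnames = list(sprintf("g%d", 1:5), des$sample_id))
  sf <- size_factors(cnt)
  disp <- fit_dispersions(cnt, sf, des)
  res <- paired_nb_wald(cnt, sf, disp, des)
  expect_true(all(abs(res$log2fc) < 1e-6))
  expect_true(all(res$pvalue > 0.999))

  # single donor, unit size factors, floor dispersion: saturated Poisson
  # closed form log2(100/50) = 1
  des1 <- paired_design(1)
  cnt1 <- matrix(c(50L, 100L), 1, dimnames = list("g1", des1$sample_id))
  disp1 <- structure(list(
    table = data.frame(guide_id = "g1", base_mean = 75, alpha_raw = 1e-8,
                       alpha_trend = 1e-8, alpha_final = 1e-8,
                       at_floor = TRUE, ok = TRUE),
    trend = c(a0 = 1e-8, a1 = 0), prior_var = 0.25, alpha_floor = 1e-8),
    class = "dispersion_model")
  res1 <- paired_nb_wald(cnt1, c(1, 1), disp1, des1)
  expect_equal(res1$log2fc, 1, tolerance = 1e-6)
  expect_gt(res1$stat, 0)
})

test_that("known log2 fold changes are recovered at depth", {
  set.seed(103)
  des <- paired_design(3)
  n <- 300
  mu_low <- 2000; mu_high <- 2000 * 4  # beta = 2 on the log2 scale
  phi <- 0.005
  cnt <- matrix(0L, n, 6)
  for (j in c(2, 4, 6)) cnt[, j] <- rnbinom(n, mu = mu_high, size = 1 / phi)
  for (j in c(1, 3, 5)) cnt[, j] <- rnbinom(n, mu = mu_low, size = 1 / phi)
  dimnames(cnt) <- list(sprintf("g%03d", 1:n), des$sample_id)
  sf <- rep(1, 6)  # equal depths by construction
  disp <- fit_dispersions(cnt, sf, des)
  res <- paired_nb_wald(cnt, sf, disp, des)
  expect_gte(mean(abs(res$log2fc - 2) < 0.2), 0.95)
})

test_that("one-sided p-values partition the two-sided test", {
  sim <- simulate_sort_screen(screen_sim_config(n_genes = 40, n_nt = 20,
                                                seed = 7))
  res <- guide_enrichment(sim$counts, sim$samples, sim$library)
  ok <- res$ok
  expect_true(all(abs(res$p_high[ok] + res$p_low[ok] - 1) < 1e-12))
  expect_equal(res$pvalue[ok], 2 * pmin(res$p_high[ok], res$p_low[ok]),
               tolerance = 1e-9)
  expect_true(all(res$pvalue[ok] >= 0 & res$pvalue[ok] <= 1))
})

test_that("statistics are invariant to consistent donor relabeling", {
  sim <- simulate_sort_screen(screen_sim_config(n_genes = 30, n_nt = 15,
                                                seed = 8))
  res1 <- guide_enrichment(sim$counts, sim$samples, sim$library)
  perm <- sim$samples
  perm$donor <- c(donor1 = "donorC", donor2 = "donorA",
                  donor3 = "donorB")[perm$donor]
  res2 <- guide_enrichment(sim$counts, perm, sim$library)
  expect_equal(res1$log2fc, res2$log2fc, tolerance = 1e-8)
  expect_equal(res1$pvalue, res2$pvalue, tolerance = 1e-8)
})

test_that("type-I error of the guide test is near nominal on null screens", {
  sim <- simulate_sort_screen(screen_sim_config(n_genes = 250, n_nt = 120,
                                                depth = 300, seed = 9))
  res <- guide_enrichment(sim$counts, sim$samples, sim$library)
  frac <- mean(res$pvalue < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.08)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(104)
  for (i in 1:5) {
    p <- runif(50)
    p[sample(50, 5)] <- NA
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("the NB machinery agrees with an independent reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(105)
  sim <- simulate_sort_screen(screen_sim_config(
    n_genes = 40, n_nt = 20, depth = 400,
    delta = sample(c(-1, 0, 0, 1), 40, replace = TRUE), seed = 11))
  ours <- guide_enrichment(sim$counts, sim$samples, sim$library)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sim$counts, S4Vectors::DataFrame(
        donor = factor(sim$samples$donor),
        bin = factor(sim$samples$bin, levels = c("LOW", "HIGH"))),
      design = ~ donor + bin)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds, contrast = c("bin", "HIGH", "LOW"))
  })
  sf_ref <- DESeq2::sizeFactors(dds)
  expect_equal(unname(size_factors(sim$counts)), unname(sf_ref),
               tolerance = 0.02)
  both <- ours$ok & !is.na(ref$log2FoldChange)
  expect_gt(cor(ours$log2fc[both], ref$log2FoldChange[both]), 0.98)
})
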