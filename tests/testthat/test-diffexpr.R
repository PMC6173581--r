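make_counts <- function(m) {
  tibble::tibble(feature_id = rownames(m)) |>
    dplyr::bind_cols(tibble::as_tibble(m))
}

test_that("size factors follow the median-of-ratios closed forms", {
  m <- matrix(c(10L, 20L, 40L, 10L, 20L, 40L), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sf <- size_factors(make_counts(m))
  expect_equal(sf$size_factor, c(1, 1))

  # sample B = 2 x sample A exactly: after rescaling to geometric mean 1 the
  # factors are (1/sqrt(2), sqrt(2))
  m2 <- cbind(A = c(10L, 50L, 200L), B = c(20L, 100L, 400L))
  rownames(m2) <- paste0("g", 1:3)
  sf2 <- size_factors(m2)
  expect_equal(sf2$size_factor, c(1 / sqrt(2), sqrt(2)))
  expect_equal(prod(sf2$size_factor), 1, tolerance = 1e-9)

  mz <- cbind(a = c(0L, 5L), b = c(3L, 0L))
  rownames(mz) <- c("g1", "g2")
  expect_error(size_factors(mz), "positive")
})

test_that("size factors recover planted depth factors and match DESeq2 up to rescaling", {
  cfg <- sim_config(n_genes = 150L, n_chroms = 1L, chrom_length = 350000L,
                    seed = 61, sf_sdlog = 0.3, rt_fraction = 0,
                    de_fraction = 0, noise_rate = 0)
  sim <- simulate_dataset(cfg)
  counts <- build_count_tables(sim$reads, sim$sample_sheet, sim$annotation,
                               NULL, l_frag = NULL)$transcripts
  sf <- size_factors(counts)
  planted <- sim$sample_sheet$size_factor
  planted <- planted / exp(mean(log(planted)))
  expect_equal(sf$size_factor, planted, tolerance = 0.05)

  skip_if_not_installed("DESeq2")
  m <- readthroughr:::as_count_matrix(counts)
  ds <- DESeq2::estimateSizeFactorsForMatrix(m)
  ds <- ds / exp(mean(log(ds)))
  # DESeq2 takes the median of log ratios; with an even number of reference
  # features the two medians interpolate differently, hence the loose tie
  expect_equal(sf$size_factor, unname(ds), tolerance = 1e-3)
})

test_that("moment dispersion: Poisson limit, zero variance, and NB recovery", {
  sheet <- tibble::tibble(sample_id = paste0("s", 1:100),
                          genotype = rep(c("a", "b"), each = 50))
  set.seed(303)
  # Poisson counts at high mean -> dispersion near the floor
  mpois <- matrix(rpois(100 * 20, 2000), nrow = 20,
                  dimnames = list(paste0("g", 1:20), sheet$sample_id))
  disp <- estimate_dispersion(make_counts(mpois), sheet)
  expect_lt(median(disp$dispersion), 1e-3)

  # constant counts -> exactly the floor
  mconst <- matrix(7L, nrow = 3, ncol = 100,
                   dimnames = list(paste0("c", 1:3), sheet$sample_id))
  dconst <- estimate_dispersion(make_counts(mconst), sheet)
  expect_equal(dconst$dispersion, rep(1e-8, 3))

  # NB alpha = 0.05, n = 50 per condition: mean estimate within [0.03, 0.07]
  mnb <- matrix(rnbinom(100 * 200, mu = 500, size = 1 / 0.05), nrow = 200,
                dimnames = list(paste0("n", 1:200), sheet$sample_id))
  dnb <- estimate_dispersion(make_counts(mnb), sheet)
  expect_gt(mean(dnb$dispersion), 0.03)
  expect_lt(mean(dnb$dispersion), 0.07)

  # one-sided shrinkage floors low estimates at the median, keeps high ones
  dshr <- estimate_dispersion(make_counts(mnb), sheet, shrink = TRUE)
  med <- median(dnb$dispersion)
  expect_true(all(dshr$dispersion >= med))
  hi <- dnb$dispersion > med
  expect_equal(dshr$dispersion[hi], dnb$dispersion[hi])
})

test_that("BH adjustment equals the brute-force step-up rule and is monotone", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (i in 1:5) {
    p <- round(runif(40), 3)
    padj <- bh_adjust(p)
    expect_equal(padj, oracle_bh(p))
    expect_true(all(padj >= p))
    # padj non-decreasing in p-rank
    expect_true(all(diff(padj[order(p)]) >= -1e-12))
  }
})

test_that("identical conditions give zero fold change and ns calls", {
  sheet <- tibble::tibble(sample_id = paste0("s", 1:6),
                          genotype = rep(c("wt", "mut"), each = 3))
  m <- matrix(rep(c(100L, 40L, 800L), 6), nrow = 3,
              dimnames = list(paste0("g", 1:3), sheet$sample_id))
  res <- nb_wald_test(make_counts(m), sheet, contrast = c("mut", "wt"))
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$call, rep("ns", 3))
  expect_equal(res$pvalue, rep(1, 3))
})

test_that("swapping condition labels negates fold changes and keeps p-values", {
  sheet <- tibble::tibble(sample_id = paste0("s", 1:6),
                          genotype = rep(c("wt", "mut"), each = 3))
  set.seed(71)
  m <- matrix(rnbinom(60, mu = 300, size = 20), nrow = 10,
              dimnames = list(paste0("g", 1:10), sheet$sample_id))
  a <- nb_wald_test(make_counts(m), sheet, contrast = c("mut", "wt"))
  b <- nb_wald_test(make_counts(m), sheet, contrast = c("wt", "mut"))
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$se, b$se)
  expect_equal(a$pvalue, b$pvalue)
})

test_that("all-zero features are flagged with p = 1", {
  sheet <- tibble::tibble(sample_id = paste0("s", 1:6),
                          genotype = rep(c("wt", "mut"), each = 3))
  m <- rbind(gz = rep(0L, 6),
             gok = c(100L, 110L, 90L, 200L, 210L, 190L))
  colnames(m) <- sheet$sample_id
  res <- nb_wald_test(make_counts(m), sheet, contrast = c("mut", "wt"))
  expect_equal(res$pvalue[res$feature_id == "gz"], 1)
  expect_equal(res$flag[res$feature_id == "gz"], "no_counts")
})

test_that("a strong true effect is detected in nearly every replicate draw", {
  # true lfc = 2 at mu = 500, alpha = 0.01, n = 3 vs 3: detected as "up" at
  # padj <= 0.05 in >= 95% of 200 simulations
  sheet <- tibble::tibble(sample_id = paste0("s", 1:6),
                          genotype = rep(c("wt", "mut"), each = 3))
  set.seed(404)
  n_bg <- 60
  detected <- replicate(200, {
    bg <- matrix(rnbinom(n_bg * 6, mu = 300, size = 1 / 0.01), nrow = n_bg)
    hit <- c(rnbinom(3, mu = 500, size = 1 / 0.01),
             rnbinom(3, mu = 2000, size = 1 / 0.01))
    m <- rbind(bg, hit)
    rownames(m) <- c(paste0("bg", seq_len(n_bg)), "hit")
    colnames(m) <- sheet$sample_id
    res <- nb_wald_test(make_counts(m), sheet, contrast = c("mut", "wt"))
    res$call[res$feature_id == "hit"] == "up"
  })
  expect_gte(mean(detected), 0.95)
})

test_that("the null simulation stays within the nominal false-call rate", {
  # 2000 features, no true effects, 3 vs 3: <= 5% of features at padj <= 0.05
  sheet <- tibble::tibble(sample_id = paste0("s", 1:6),
                          genotype = rep(c("wt", "mut"), each = 3))
  set.seed(505)
  mu <- rlnorm(2000, log(150), 1)
  m <- matrix(rnbinom(2000 * 6, mu = rep(mu, 6), size = 1 / 0.05),
              nrow = 2000, dimnames = list(paste0("g", 1:2000),
                                           sheet$sample_id))
  res <- nb_wald_test(make_counts(m), sheet, contrast = c("mut", "wt"))
  expect_lte(mean(res$padj <= 0.05), 0.05)
})

test_that("classification uses strict fold-change and non-strict FDR thresholds", {
  res <- tibble::tibble(
    feature_id = c("at", "above", "pborder", "pfail"),
    log2fc = c(0.5, 0.6, 0.7, 0.8),
    padj = c(0.01, 0.04, 0.05, 0.051))
  cls <- classify_de(res)
  calls <- setNames(cls$call, cls$feature_id)
  expect_equal(unname(calls["at"]), "ns")      # exactly 0.5 is not "superior"
  expect_equal(unname(calls["above"]), "up")
  expect_equal(unname(calls["pborder"]), "up") # FDR <= 0.05 inclusive
  expect_equal(unname(calls["pfail"]), "ns")
  down <- classify_de(dplyr::mutate(res, log2fc = -log2fc))
  expect_equal(down$call, c("ns", "down", "down", "ns"))
  sets <- de_sets(cls)
  expect_equal(sort(sets$up), c("above", "pborder"))
  expect_equal(sets$down, character(0))
})

test_that("tidy and glance summarise DE results", {
  sheet <- tibble::tibble(sample_id = paste0("s", 1:6),
                          genotype = rep(c("wt", "mut"), each = 3))
  set.seed(8)
  m <- matrix(rnbinom(30, mu = 200, size = 20), nrow = 5,
              dimnames = list(paste0("g", 1:5), sheet$sample_id))
  res <- nb_wald_test(make_counts(m), sheet, contrast = c("mut", "wt"))
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "rt_de_result"))
  gl <- generics::glance(res)
  expect_equal(gl$n_features, 5)
  expect_equal(gl$contrast, "mut vs wt")
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
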