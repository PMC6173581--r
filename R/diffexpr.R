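#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (positive in
#' every sample) of the ratio of the feature's count to its geometric mean
#' across samples; factors are then rescaled to geometric mean 1. Audit rows
#' (ids starting with `__`) are ignored.
#'
#' @param counts Count table tibble (`feature_id`, optional `length`, sample
#'   columns) or a numeric matrix with feature row names.
#' @return Tibble with `sample_id` and `size_factor`.
#' @export
size_factors <- function(counts) {
  m <- as_count_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    abort(paste("no feature has positive counts in every sample;",
                "consider a pseudo-reference (e.g. add a pseudocount)"))
  }
  mp <- m[pos, , drop = FALSE]
  gm <- exp(rowMeans(log(mp)))
  sf <- apply(mp / gm, 2, median)
  sf <- sf / geomean(sf)
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

# count tibble or matrix -> integer matrix, dropping audit rows
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    m <- counts
  } else {
    assert_cols(counts, "feature_id", "counts")
    df <- as_tibble(counts)
    samp <- setdiff(names(df), c("feature_id", "length"))
    m <- as.matrix(df[samp])
    rownames(m) <- df$feature_id
  }
  if (is.null(rownames(m))) {
    abort("count matrix must carry feature row names")
  }
  m[!startsWith(rownames(m), "__"), , drop = FALSE]
}

#' Method-of-moments negative-binomial dispersion per feature
#'
#' On size-factor-normalised counts, per condition with at least two
#' replicates: `alpha = (s^2 - mu) / mu^2`, averaged across conditions and
#' floored at `alpha_min`. Constant or under-dispersed features fall to the
#' floor (the Poisson limit).
#'
#' With `shrink = TRUE`, per-feature estimates are
#' additionally raised to the median estimate across features when they fall
#' below it — a one-sided shrinkage toward the trend median that guards
#' against the severe underestimation the moment estimator suffers at
#' triplicate scale (where a feature's three counts can sit close together by
#' chance, yielding a near-zero dispersion and an anti-conservative Wald
#' test). Estimates above the median are kept as they are.
#'
#' @param counts Count table (see [size_factors()]).
#' @param sample_sheet Tibble with `sample_id` and `genotype` columns
#'   matching the count columns.
#' @param sf Optional precomputed [size_factors()] tibble.
#' @param alpha_min Dispersion floor.
#' @param shrink Raise per-feature estimates to the across-feature median
#'   (one-sided shrinkage toward the trend median).
#' @return Tibble with `feature_id` and `dispersion`.
#' @export
estimate_dispersion <- function(counts, sample_sheet, sf = NULL,
                                alpha_min = 1e-8, shrink = FALSE) {
  m <- as_count_matrix(counts)
  sf <- sf %||% size_factors(counts)
  sfv <- setNames(sf$size_factor, sf$sample_id)[colnames(m)]
  norm <- sweep(m, 2, sfv, "/")
  conds <- split(sample_sheet$sample_id, sample_sheet$genotype)
  conds <- conds[lengths(conds) >= 2]
  if (length(conds) == 0) abort("need >= 2 replicates in some condition")
  per_cond <- purrr::map(conds, function(ids) {
    x <- norm[, ids, drop = FALSE]
    mu <- rowMeans(x)
    v <- apply(x, 1, stats::var)
    ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  })
  alpha <- rowMeans(do.call(cbind, per_cond), na.rm = TRUE)
  alpha[is.nan(alpha)] <- alpha_min
  alpha <- pmax(alpha, alpha_min)
  if (shrink && length(alpha) > 1) {
    alpha <- pmax(alpha, median(alpha))
  }
  tibble(feature_id = rownames(m), dispersion = unname(alpha))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `padj_i = min over j with p_j >= p_i of
#' m * p_j / rank_j`, capped at 1.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1] and contain no NA")
  }
  p.adjust(pvals, method = "BH")
}

#' Negative-binomial Wald test against a log2 fold-change threshold
#'
#' Two-group comparison of size-factor-normalised NB counts. Per feature, the
#' log2 fold change `beta = log2(mu_mut / mu_ref)` gets a standard error from
#' the NB variance `mu + alpha mu^2` by the delta method, and the thresholded
#' Wald p-value is `2 * P(Z > (|beta| - theta) / SE)` when `|beta| > theta`
#' (1 otherwise) for the two-sided test, or `P(Z > (beta - theta) / SE)` for
#' the one-sided (`alternative = "greater"`) read-through presence test at
#' `theta = 0`. P-values are BH-adjusted within the analysis. A pseudocount
#' of 0.5 stabilises means of all-zero conditions; features with zero counts
#' in both conditions are reported with p = 1 and flagged.
#'
#' @param counts Count table (see [size_factors()]).
#' @param sample_sheet Tibble with `sample_id` and `genotype`.
#' @param contrast Character vector `c(mutant, reference)` naming genotypes.
#' @param lfc_threshold Threshold theta on the log2 scale (0.5 for
#'   differential expression, 0 for read-through presence).
#' @param alternative `"two.sided"` or `"greater"`.
#' @param alpha FDR level used for the `call` column.
#' @param sf,dispersion Optional precomputed [size_factors()] /
#'   [estimate_dispersion()] tibbles.
#' @param dispersion_shrink Passed to [estimate_dispersion()] as `shrink`
#'   when dispersions are not supplied; off by default (the thresholded test
#'   is conservative by construction), available as a robustness option for
#'   noisy designs.
#' @return Tibble of class `rt_de_result` with `feature_id`, `base_mean`,
#'   `log2fc`, `se`, `stat`, `pvalue`, `padj`, `call` (up/down/ns) and
#'   `flag`.
#' @export
nb_wald_test <- function(counts, sample_sheet,
                         contrast, lfc_threshold = 0.5,
                         alternative = c("two.sided", "greater"),
                         alpha = 0.05, sf = NULL, dispersion = NULL,
                         dispersion_shrink = FALSE) {
  alternative <- match.arg(alternative)
  if (length(contrast) != 2) abort("`contrast` must be c(mutant, reference)")
  if (!all(contrast %in% sample_sheet$genotype)) {
    abort("contrast genotypes absent from the sample sheet")
  }
  m <- as_count_matrix(counts)
  sheet <- filter(sample_sheet, .data$genotype %in% contrast)
  m <- m[, sheet$sample_id, drop = FALSE]
  sf <- sf %||% size_factors(m)
  disp <- dispersion %||% estimate_dispersion(m, sheet, sf = sf,
                                              shrink = dispersion_shrink)
  sfv <- setNames(sf$size_factor, sf$sample_id)[colnames(m)]
  alpha_v <- setNames(disp$dispersion, disp$feature_id)[rownames(m)]

  ids_mut <- sheet$sample_id[sheet$genotype == contrast[1]]
  ids_ref <- sheet$sample_id[sheet$genotype == contrast[2]]
  norm <- sweep(m, 2, sfv, "/")
  mu_mut <- rowMeans(norm[, ids_mut, drop = FALSE])
  mu_ref <- rowMeans(norm[, ids_ref, drop = FALSE])
  base_mean <- rowMeans(norm)

  # delta-method variance of log2 of a condition mean of normalised NB counts
  log2_var <- function(mu, ids) {
    mu_t <- mu + 0.5
    v <- purrr::map_dbl(seq_along(mu_t), function(i) {
      sum(mu_t[i] / sfv[ids] + alpha_v[i] * mu_t[i]^2) / length(ids)^2
    })
    v / (mu_t^2 * log(2)^2)
  }
  beta <- log2((mu_mut + 0.5) / (mu_ref + 0.5))
  se <- sqrt(log2_var(mu_mut, ids_mut) + log2_var(mu_ref, ids_ref))
  if (alternative == "two.sided") {
    stat <- (abs(beta) - lfc_threshold) / se
    p <- ifelse(abs(beta) > lfc_threshold,
                2 * pnorm(stat, lower.tail = FALSE), 1)
  } else {
    stat <- (beta - lfc_threshold) / se
    p <- pnorm(stat, lower.tail = FALSE)
  }
  empty <- mu_mut == 0 & mu_ref == 0
  p[empty] <- 1
  p <- pmin(p, 1)
  padj <- bh_adjust(p)
  res <- tibble(
    feature_id = rownames(m),
    base_mean = unname(base_mean),
    log2fc = unname(beta),
    se = unname(se),
    stat = unname(stat),
    pvalue = unname(p),
    padj = unname(padj),
    flag = if_else(unname(empty), "no_counts", "ok")
  )
  res <- mutate(res, call = de_call(.data$log2fc, .data$padj,
                                    lfc_threshold, alpha, alternative))
  structure(res,
            contrast = contrast, lfc_threshold = lfc_threshold,
            alternative = alternative, alpha = alpha,
            class = c("rt_de_result", class(tibble())))
}

de_call <- function(log2fc, padj, lfc, alpha, alternative = "two.sided") {
  if (alternative == "greater") {
    if_else(log2fc > lfc & padj <= alpha, "up", "ns")
  } else {
    dplyr::case_when(
      log2fc > lfc & padj <= alpha ~ "up",
      log2fc < -lfc & padj <= alpha ~ "down",
      TRUE ~ "ns")
  }
}

#' Classify features as up/down at fold-change and FDR thresholds
#'
#' Strict inequalities on the fold change (`log2fc > lfc` / `< -lfc`),
#' non-strict on the adjusted p-value (`padj <= alpha`), matching "log2 fold
#' change superior to 0.5 or inferior to -0.5, FDR <= 0.05".
#'
#' @param results An [nb_wald_test()] result (or any tibble with `log2fc`
#'   and `padj`).
#' @param lfc Fold-change threshold (log2).
#' @param alpha FDR level.
#' @return The input tibble with a recomputed `call` column.
#' @export
classify_de <- function(results, lfc = 0.5, alpha = 0.05) {
  assert_cols(results, c("log2fc", "padj"), "results")
  mutate(as_tibble(results),
         call = de_call(.data$log2fc, .data$padj, lfc, alpha))
}

#' Up/down feature sets from a classified DE result
#'
#' @param results A tibble with `feature_id` and `call`.
#' @return Named list with character vectors `up` and `down`.
#' @export
de_sets <- function(results) {
  list(up = results$feature_id[results$call == "up"],
       down = results$feature_id[results$call == "down"])
}

#' Write a DE result as TSV (volcano-ready columns)
#'
#' @param results An [nb_wald_test()] result.
#' @param path Output path.
#' @export
write_de_table <- function(results, path) {
  readr::write_tsv(as_tibble(results), path, progress = FALSE)
  invisible(results)
}
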