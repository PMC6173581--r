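#' Hypergeometric upper-tail test of a gene-set overlap
#'
#' Probability of observing an overlap of at least `k` between a set of size
#' `n1` and a set of size `n2` drawn from a universe of `N` features:
#' `P(X >= k)` with `X ~ Hypergeometric(N, n1, n2)`.
#'
#' @param k Observed overlap.
#' @param n1,n2 Set sizes.
#' @param N Universe size.
#' @return One-row tibble with `k`, `n1`, `n2`, `N`, `p_value`.
#' @export
hypergeometric_overlap <- function(k, n1, n2, N) {
  if (k > min(n1, n2) || n1 > N || n2 > N || k < 0 || min(n1, n2, N) < 0) {
    abort("inconsistent arguments: need 0 <= k <= min(n1, n2) and n1, n2 <= N")
  }
  p <- phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
  tibble(k = k, n1 = n1, n2 = n2, N = N, p_value = p)
}

#' Pearson chi-square test of enrichment on a 2x2 table
#'
#' Chi-square without continuity correction on the table
#' `rbind(c(a, b), c(c, d))`, 1 degree of freedom.
#'
#' @param a,b,c,d Non-negative counts; all margins must be positive.
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
chisq_enrichment <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(tab < 0)) abort("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("all table margins must be positive")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value))
}

#' Orientation composition of a gene set against the genome background
#'
#' Counts and fractions of convergent / tandem / divergent / isolated genes
#' within a gene set, next to the genome-wide composition.
#'
#' @param gene_set Character vector of gene ids (all must exist in `ann`).
#' @param ann A [genome_annotation()].
#' @param allow_empty If `FALSE` (default), an empty set is an error;
#'   otherwise an all-zero report is returned.
#' @return Tibble with `orientation`, `n_set`, `frac_set`, `n_genome`,
#'   `frac_genome`.
#' @export
orientation_composition <- function(gene_set, ann, allow_empty = FALSE) {
  unknown <- setdiff(gene_set, ann$gene_id)
  if (length(unknown) > 0) {
    abort(sprintf("gene id(s) not in annotation: %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  if (length(gene_set) == 0 && !allow_empty) abort("`gene_set` is empty")
  ori <- classify_orientation(ann)
  genome <- dplyr::count(ori, .data$orientation, .drop = FALSE,
                         name = "n_genome")
  inset <- ori |>
    filter(.data$gene_id %in% gene_set) |>
    dplyr::count(.data$orientation, .drop = FALSE, name = "n_set")
  inner_join(inset, genome, by = "orientation") |>
    mutate(frac_set = if (sum(.data$n_set) > 0) .data$n_set / sum(.data$n_set)
                      else 0,
           frac_genome = .data$n_genome / sum(.data$n_genome)) |>
    select("orientation", "n_set", "frac_set", "n_genome", "frac_genome")
}

#' Compare two genotypes' DE and read-through results
#'
#' Summarises two differential-expression analyses and two read-through call
#' sets built against the same annotation: up/down counts per genotype,
#' overlaps of the up and down sets with hypergeometric p-values (universe =
#' features tested in both analyses), Pearson correlation of log2 fold
#' changes across all shared features, biotype composition of each set, and
#' read-through counts and overlap.
#'
#' @param de_a,de_b [nb_wald_test()] results for the two genotypes.
#' @param rt_a,rt_b `rt_calls` tibbles for the two genotypes (may be empty).
#' @param ann A [genome_annotation()].
#' @param labels Length-2 character vector naming the genotypes.
#' @return List of class `rt_comparison` with one-row `summary` tibble and a
#'   `biotypes` composition tibble.
#' @export
summarise_comparison <- function(de_a, de_b, rt_a, rt_b, ann,
                                 labels = c("a", "b")) {
  rt_a <- rt_a %||% empty_rt_calls()
  rt_b <- rt_b %||% empty_rt_calls()
  shared <- intersect(de_a$feature_id, de_b$feature_id)
  if (length(shared) == 0) {
    abort("the two DE results share no features; were they built against the same annotation?")
  }
  sets_a <- de_sets(de_a)
  sets_b <- de_sets(de_b)
  N <- length(shared)
  ov <- function(x, y) {
    k <- length(intersect(x, y))
    n1 <- length(intersect(x, shared))
    n2 <- length(intersect(y, shared))
    p <- if (n1 > 0 && n2 > 0) {
      hypergeometric_overlap(length(intersect(intersect(x, shared),
                                              intersect(y, shared))),
                             n1, n2, N)$p_value
    } else NA_real_
    list(k = k, p = p)
  }
  up_ov <- ov(sets_a$up, sets_b$up)
  down_ov <- ov(sets_a$down, sets_b$down)
  lfc <- inner_join(select(as_tibble(de_a), "feature_id", lfc_a = "log2fc"),
                    select(as_tibble(de_b), "feature_id", lfc_b = "log2fc"),
                    by = "feature_id")
  rt_genes_a <- unique(as_tibble(rt_a)$gene_id)
  rt_genes_b <- unique(as_tibble(rt_b)$gene_id)
  rt_k <- length(intersect(rt_genes_a, rt_genes_b))
  rt_p <- if (length(rt_genes_a) > 0 && length(rt_genes_b) > 0) {
    hypergeometric_overlap(length(intersect(intersect(rt_genes_a, ann$gene_id),
                                            intersect(rt_genes_b, ann$gene_id))),
                           length(intersect(rt_genes_a, ann$gene_id)),
                           length(intersect(rt_genes_b, ann$gene_id)),
                           nrow(ann))$p_value
  } else NA_real_

  biotype_of <- setNames(ann$biotype, ann$gene_id)
  bio <- purrr::imap_dfr(
    list(up_a = sets_a$up, down_a = sets_a$down,
         up_b = sets_b$up, down_b = sets_b$down,
         rt_a = rt_genes_a, rt_b = rt_genes_b),
    function(genes, nm) {
      genes <- intersect(genes, ann$gene_id)
      if (length(genes) == 0) return(NULL)
      tibble(set = nm, biotype = unname(biotype_of[genes])) |>
        dplyr::count(.data$set, .data$biotype, name = "n") |>
        mutate(fraction = .data$n / sum(.data$n))
    })

  summary <- tibble(
    genotype_a = labels[1], genotype_b = labels[2],
    n_tested = N,
    n_up_a = length(sets_a$up), n_down_a = length(sets_a$down),
    n_up_b = length(sets_b$up), n_down_b = length(sets_b$down),
    overlap_up = up_ov$k, p_overlap_up = up_ov$p,
    overlap_down = down_ov$k, p_overlap_down = down_ov$p,
    lfc_correlation = cor(lfc$lfc_a, lfc$lfc_b),
    n_rt_a = length(rt_genes_a), n_rt_b = length(rt_genes_b),
    rt_overlap = rt_k, p_rt_overlap = rt_p
  )
  structure(list(summary = summary, biotypes = bio),
            class = "rt_comparison")
}

#' @export
print.rt_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("# Transcriptome comparison: %s vs %s (universe %d features)\n",
              s$genotype_a, s$genotype_b, s$n_tested))
  cat(sprintf("  up: %d vs %d (overlap %d, p = %.3g)\n",
              s$n_up_a, s$n_up_b, s$overlap_up, s$p_overlap_up))
  cat(sprintf("  down: %d vs %d (overlap %d)\n",
              s$n_down_a, s$n_down_b, s$overlap_down))
  cat(sprintf("  log2FC correlation: %.3f\n", s$lfc_correlation))
  cat(sprintf("  read-throughs: %d vs %d (overlap %d, p = %.3g)\n",
              s$n_rt_a, s$n_rt_b, s$rt_overlap, s$p_rt_overlap))
  invisible(x)
}
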