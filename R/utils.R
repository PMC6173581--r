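# Internal helpers shared across modules. Coordinates are 0-based half-open
# everywhere inside the package; conversion to/from 1-based closed happens only
# at the GFF3/GRanges boundary.

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_stranded <- function(df, what = "intervals") {
  bad <- !df$strand %in% c("+", "-")
  if (any(bad)) {
    abort(sprintf("%d %s have no definite strand (must be '+' or '-')",
                  sum(bad), what))
  }
  invisible(df)
}

#' @noRd
chrom_sizes_of <- function(x) {
  cs <- attr(x, "chrom_sizes", exact = TRUE)
  if (is.null(cs)) abort("object carries no `chrom_sizes` attribute")
  cs
}

# tibble (0-based half-open) -> GRanges (1-based closed). Unstranded rows map
# to "*".
as_granges0 <- function(df, chrom_sizes = NULL) {
  strand <- if ("strand" %in% names(df)) {
    ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  } else "*"
  seqlev <- if (!is.null(chrom_sizes)) names(chrom_sizes) else unique(df$chrom)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = seqlev),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes[GenomeInfoDb::seqlevels(gr)])
  }
  gr
}

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

# deterministic child seed derived from a base seed and a stage label; keeps
# results below .Machine$integer.max
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

round_half_up <- function(x) floor(x + 0.5)
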