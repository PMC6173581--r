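#' Parameters of the intergenic broad-peak scan
#'
#' The scan mirrors the parameter surface of the Music broad-peak caller as
#' used for intergenic RNA-seq signal: window lengths grow geometrically from
#' `begin_l` to `end_l` by factor `step`, reads are extended to `l_frag`
#' bases, and `q_threshold = 1` keeps every window that passes the
#' fold-change gate (no q-value filtering). Internally the multiscale
#' decomposition is a sliding-window Poisson scan against a per-strand
#' background rate with Benjamini-Hochberg correction; see the methods
#' vignette.
#'
#' @param begin_l Smallest window length (bases).
#' @param end_l Largest window length (bases).
#' @param step Geometric scale factor between window lengths (> 1).
#' @param l_frag Fragment extension length applied to each read in its 3'
#'   direction before computing coverage.
#' @param l_mapp Read length used for mappability bookkeeping; recorded but
#'   not otherwise used (no mappability track at desk scale).
#' @param q_threshold BH-adjusted p-value cutoff in (0, 1]; 1 disables
#'   q-value filtering.
#' @param min_fold_change Minimal window enrichment over the expected
#'   background count.
#' @return A list of class `peak_params`.
#' @export
peak_params <- function(begin_l = 50L, end_l = 500L, step = 1.1,
                        l_frag = 363L, l_mapp = 50L, q_threshold = 1,
                        min_fold_change = 2) {
  if (begin_l > end_l) abort("`begin_l` must be <= `end_l`")
  if (step <= 1) abort("`step` must be > 1")
  if (q_threshold <= 0 || q_threshold > 1) abort("`q_threshold` must be in (0, 1]")
  structure(as.list(environment()), class = "peak_params")
}

#' Per-base stranded coverage from reads
#'
#' Each read is (optionally) extended to `l_frag` bases in its 3' direction,
#' clipped at chromosome bounds, and per-base counts are accumulated per
#' strand. The result is run-length encoded in bedGraph form (zero-depth runs
#' omitted).
#'
#' @param reads Data frame with `chrom`, `start`, `end`, `strand`.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param l_frag Fragment extension length; `NULL` leaves reads unextended.
#' @return Tibble of class `stranded_coverage` with `chrom`, `start`, `end`,
#'   `strand`, `depth` and a `chrom_sizes` attribute.
#' @export
coverage_from_reads <- function(reads, chrom_sizes, l_frag = 363L) {
  assert_cols(reads, c("chrom", "start", "end", "strand"), "reads")
  frags <- extend_to_fragments(reads, chrom_sizes, l_frag)
  if (nrow(frags) == 0) {
    return(structure(
      tibble(chrom = character(), start = integer(), end = integer(),
             strand = character(), depth = integer()),
      chrom_sizes = chrom_sizes,
      class = c("stranded_coverage", class(tibble()))))
  }
  out <- purrr::map_dfr(
    split(frags, list(frags$chrom, frags$strand), drop = TRUE),
    function(f) {
      len <- unname(chrom_sizes[[f$chrom[1]]])
      cov <- IRanges::coverage(IRanges::IRanges(f$start + 1L, f$end),
                               width = len)
      ends <- cumsum(S4Vectors::runLength(cov))
      tibble(chrom = f$chrom[1],
             start = c(0L, head(ends, -1)),
             end = as.integer(ends),
             strand = f$strand[1],
             depth = as.integer(S4Vectors::runValue(cov)))
    }) |>
    filter(.data$depth > 0) |>
    arrange(.data$chrom, .data$strand, .data$start)
  structure(out, chrom_sizes = chrom_sizes,
            class = c("stranded_coverage", class(tibble())))
}

# extend reads to l_frag in their 3' direction (no-op when l_frag is NULL)
extend_to_fragments <- function(reads, chrom_sizes, l_frag) {
  assert_stranded(reads, "reads")
  r <- as_tibble(reads)
  if (!is.null(l_frag)) {
    r <- mutate(r,
      end = if_else(.data$strand == "+",
                    pmin(.data$start + as.integer(l_frag),
                         unname(chrom_sizes[.data$chrom])),
                    .data$end),
      start = if_else(.data$strand == "-",
                      pmax(.data$end - as.integer(l_frag), 0L),
                      .data$start))
  }
  r
}

#' Write / read per-strand coverage as bedGraph
#'
#' @param cov A coverage tibble (one strand per file, as conventional for
#'   stranded bedGraph tracks).
#' @param path File path.
#' @return The input, invisibly (`read_bedgraph()` returns a tibble).
#' @export
write_bedgraph <- function(cov, path) {
  readr::write_tsv(select(as_tibble(cov), "chrom", "start", "end", "depth"),
                   path, col_names = FALSE, progress = FALSE)
  invisible(cov)
}

#' @rdname write_bedgraph
#' @param strand Strand to attach to the intervals read back.
#' @export
read_bedgraph <- function(path, strand) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "depth"),
                  col_types = "ciii", progress = FALSE) |>
    mutate(strand = strand, .before = "depth")
}

#' Background coverage rate within searched regions
#'
#' The background rate per strand is total coverage within the regions
#' divided by total region length, floored at one count per total region
#' length so that a zero-signal strand never yields a degenerate zero rate.
#'
#' @param cov A [coverage_from_reads()] result.
#' @param regions Stranded intervals (typically the annotation complement).
#' @return Tibble with one row per strand present in `regions`: `strand`,
#'   `rate`, `total_coverage`, `total_length`.
#' @export
estimate_background <- function(cov, regions) {
  assert_cols(regions, c("chrom", "start", "end", "strand"), "regions")
  if (nrow(regions) == 0) abort("`regions` is empty")
  purrr::map_dfr(split(as_tibble(regions), regions$strand), function(reg) {
    cv <- filter(as_tibble(cov), .data$strand == reg$strand[1])
    total_len <- sum(reg$end - reg$start)
    gr_reg <- as_granges0(reg)
    gr_cov <- as_granges0(cv)
    hits <- GenomicRanges::findOverlaps(gr_cov, gr_reg, ignore.strand = TRUE)
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gr_cov)[S4Vectors::queryHits(hits)],
      IRanges::ranges(gr_reg)[S4Vectors::subjectHits(hits)]))
    total_cov <- sum(as.numeric(ov) * cv$depth[S4Vectors::queryHits(hits)])
    tibble(strand = reg$strand[1],
           rate = max(total_cov, 1) / total_len,
           total_coverage = total_cov,
           total_length = total_len)
  })
}

# geometric ladder of window lengths
window_ladder <- function(params) {
  l <- params$begin_l
  out <- integer(0)
  while (round(l) <= params$end_l) {
    out <- c(out, as.integer(round(l)))
    l <- l * params$step
  }
  unique(out)
}

#' Call broad peaks in stranded coverage restricted to given regions
#'
#' Slides windows of geometrically increasing lengths within each region.
#' A window is significant when its coverage count reaches
#' `min_fold_change` times the expected background count and its Poisson
#' upper-tail p-value survives Benjamini-Hochberg at `q_threshold`
#' (`q_threshold = 1` keeps every fold-passing window). Significant windows
#' from all scales are merged per strand into maximal peaks scored by the
#' best window's -log10 p.
#'
#' @param cov A [coverage_from_reads()] result (fragment-extended).
#' @param regions Stranded intervals to scan (the annotation complement).
#' @param params A [peak_params()].
#' @param background Optional precomputed [estimate_background()] tibble.
#' @return Tibble of peaks: `chrom`, `start`, `end`, `strand`, `score`.
#' @export
call_peaks <- function(cov, regions, params = peak_params(),
                       background = NULL) {
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), score = double()))
  }
  empty_peaks <- tibble(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        score = double())
  chrom_sizes <- chrom_sizes_of(cov)
  bg <- background %||% estimate_background(cov, regions)
  ladder <- window_ladder(params)
  purrr::map_dfr(split(as_tibble(regions), regions$strand), function(reg) {
    st <- reg$strand[1]
    lambda <- bg$rate[bg$strand == st]
    if (length(lambda) == 0) abort(sprintf("no background rate for strand %s", st))
    wins <- purrr::map_dfr(split(reg, reg$chrom), function(rchr) {
      chr <- rchr$chrom[1]
      len <- unname(chrom_sizes[[chr]])
      cv <- filter(as_tibble(cov), .data$chrom == chr, .data$strand == st)
      vec <- integer(len)
      for (j in seq_len(nrow(cv))) {
        vec[(cv$start[j] + 1L):cv$end[j]] <- cv$depth[j]
      }
      csum <- c(0, cumsum(as.numeric(vec)))
      acc_start <- list(); acc_len <- list()
      for (l in ladder) {
        stride <- max(1L, l %/% 2L)
        ok <- rchr$end - rchr$start >= l
        if (!any(ok)) next
        starts <- unlist(purrr::map2(rchr$start[ok], rchr$end[ok], function(rs, re) {
          s <- seq.int(rs, re - l, by = stride)
          if (s[length(s)] != re - l) s <- c(s, re - l)
          s
        }))
        acc_start[[length(acc_start) + 1L]] <- starts
        acc_len[[length(acc_len) + 1L]] <- rep.int(l, length(starts))
      }
      if (length(acc_start) == 0) return(NULL)
      starts <- unlist(acc_start)
      lens <- unlist(acc_len)
      counts <- csum[starts + lens + 1] - csum[starts + 1]
      tibble(chrom = chr, start = starts, end = starts + lens,
             count = counts, expected = lambda * lens)
    })
    if (nrow(wins) == 0) return(NULL)
    wins <- mutate(wins,
                   p = ppois(.data$count - 1, .data$expected,
                             lower.tail = FALSE),
                   fold_ok = .data$count >= params$min_fold_change *
                     .data$expected & .data$count > 0)
    wins <- filter(wins, .data$fold_ok)
    if (nrow(wins) == 0) return(NULL)
    wins <- mutate(wins, padj = bh_adjust(.data$p)) |>
      filter(.data$padj <= params$q_threshold)
    if (nrow(wins) == 0) return(NULL)
    merge_windows(wins, st)
  }) |>
    bind_rows(empty_peaks) |>
    arrange(.data$chrom, .data$start)
}

# merge overlapping significant windows into maximal peaks; score = best
# window's -log10 p (p floored to avoid infinities)
merge_windows <- function(wins, strand) {
  purrr::map_dfr(split(wins, wins$chrom), function(w) {
    ir <- IRanges::IRanges(w$start + 1L, w$end)
    merged <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(ir, merged)
    score <- tapply(-log10(pmax(w$p[S4Vectors::queryHits(hits)], 1e-300)),
                    S4Vectors::subjectHits(hits), max)
    tibble(chrom = w$chrom[1],
           start = IRanges::start(merged) - 1L,
           end = IRanges::end(merged),
           strand = strand,
           score = as.numeric(score))
  })
}
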