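#' Remove reads overlapping annotated transcription units on the same strand
#'
#' First step of read-through detection: only reads with zero overlap with
#' any same-strand transcription unit are retained, so that downstream peak
#' calling sees purely intergenic (or antisense) signal.
#'
#' @param reads Data frame with `chrom`, `start`, `end`, `strand`.
#' @param ann A [genome_annotation()].
#' @return The retained reads tibble (same columns as input).
#' @export
subtract_annotated <- function(reads, ann) {
  assert_cols(reads, c("chrom", "start", "end", "strand"), "reads")
  if (nrow(reads) == 0) return(as_tibble(reads))
  gr_reads <- as_granges0(reads)
  gr_ann <- as_granges0(ann)
  hit <- IRanges::overlapsAny(gr_reads, gr_ann, ignore.strand = FALSE)
  as_tibble(reads)[!hit, ]
}

#' Keep peaks that start within two read lengths of the nearest TTS
#'
#' Applies the TTS-proximity filter: a peak is kept only when its 5'
#' boundary lies at most `2 * read_length` bases downstream of the nearest
#' same-strand TTS (the exclusion rule drops peaks starting farther away).
#' Kept peaks are paired with their assigned gene. A peak reaching into a
#' downstream same-strand transcription unit is truncated at that unit's 5'
#' boundary; a peak entirely inside same-strand annotation is dropped.
#'
#' @param peaks A [call_peaks()] result (stranded intervals).
#' @param ann A [genome_annotation()].
#' @param read_length Read length in nt (default 50, so the cutoff is 100).
#' @return Tibble of kept peaks with `gene_id`, `tts`, `tts_distance`
#'   appended and boundaries possibly truncated.
#' @export
filter_peaks_by_tts <- function(peaks, ann, read_length = 50L) {
  if (nrow(peaks) == 0) {
    return(mutate(as_tibble(peaks), gene_id = character(0),
                  tts = integer(0), tts_distance = integer(0)))
  }
  assigned <- nearest_tts_assignment(peaks, ann) |>
    filter(!is.na(.data$tts_distance),
           .data$tts_distance <= 2L * read_length)
  if (nrow(assigned) == 0) return(assigned)
  truncate_at_downstream_gene(assigned, ann)
}

# truncate peak far boundaries at the 5' boundary of the first same-strand
# unit they reach into; peaks left with non-positive width (fully covered by
# same-strand annotation) are dropped
truncate_at_downstream_gene <- function(peaks, ann) {
  if (nrow(peaks) == 0) return(as_tibble(peaks))
  units <- as_tibble(ann)
  out <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    u <- units[units$chrom == p$chrom & units$strand == p$strand &
                 units$start < p$end & units$end > p$start, ]
    if (nrow(u) == 0) return(p)
    if (p$strand == "+") {
      p$end <- min(p$end, min(u$start))
    } else {
      p$start <- max(p$start, max(u$end))
    }
    p
  })
  filter(out, .data$end > .data$start)
}

#' Consensus read-through calls across biological replicates
#'
#' A gene's read-through is retained when peaks assigned to it occur in at
#' least `min_support` replicates. Within a replicate, the farthest peak
#' boundary for the gene is used; the consensus extension runs from the TTS
#' to the median far boundary over supporting replicates (rounded half up).
#'
#' @param per_replicate_calls List of [filter_peaks_by_tts()] results, one
#'   per biological replicate.
#' @param min_support Minimal number of supporting replicates (default 2,
#'   i.e. 2 of 3).
#' @param ann A [genome_annotation()], used to guard extensions against
#'   downstream same-strand units after taking the median.
#' @return Tibble of class `rt_calls`: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tts`, `n_support`. Extensions begin exactly at the TTS.
#' @export
replicate_consensus <- function(per_replicate_calls, min_support = 2L,
                                ann = NULL) {
  if (min_support > length(per_replicate_calls)) {
    abort("`min_support` exceeds the number of replicate call sets")
  }
  per_gene <- purrr::imap_dfr(per_replicate_calls, function(calls, i) {
    if (nrow(calls) == 0) return(NULL)
    calls |>
      group_by(.data$gene_id, .data$chrom, .data$strand, .data$tts) |>
      summarise(far = if (first(.data$strand) == "+") max(.data$end)
                      else min(.data$start),
                .groups = "drop") |>
      mutate(replicate = i)
  })
  if (nrow(per_gene) == 0) {
    return(empty_rt_calls())
  }
  cons <- per_gene |>
    group_by(.data$gene_id, .data$chrom, .data$strand, .data$tts) |>
    summarise(n_support = dplyr::n_distinct(.data$replicate),
              far = as.integer(round_half_up(median(.data$far))),
              .groups = "drop") |>
    filter(.data$n_support >= min_support) |>
    mutate(start = if_else(.data$strand == "+", .data$tts, .data$far),
           end = if_else(.data$strand == "+", .data$far, .data$tts)) |>
    filter(.data$end > .data$start) |>
    select("gene_id", "chrom", "start", "end", "strand", "tts", "n_support") |>
    arrange(.data$chrom, .data$start)
  if (!is.null(ann)) {
    cons <- truncate_at_downstream_gene(cons, ann)
  }
  structure(cons, class = c("rt_calls", class(tibble())))
}

empty_rt_calls <- function() {
  structure(tibble(gene_id = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character(),
                   tts = integer(), n_support = integer()),
            class = c("rt_calls", class(tibble())))
}

#' Merge read-through annotations from two genotypes
#'
#' Union keyed by gene id; when both genotypes call the same gene, the merged
#' extension is the union span (TTS to the farther boundary). Output sorted
#' by chromosome and start, ready for joint quantification.
#'
#' @param a,b `rt_calls` tibbles built against the same annotation.
#' @return A merged `rt_calls` tibble.
#' @export
merge_genotype_annotations <- function(a, b) {
  both <- bind_rows(as_tibble(a), as_tibble(b))
  if (nrow(both) == 0) return(empty_rt_calls())
  conflict <- both |>
    distinct(.data$gene_id, .data$chrom, .data$strand, .data$tts) |>
    dplyr::count(.data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    abort(sprintf(
      "gene(s) annotated inconsistently between the two call sets: %s",
      paste(head(conflict$gene_id, 3), collapse = ", ")))
  }
  merged <- both |>
    group_by(.data$gene_id, .data$chrom, .data$strand, .data$tts) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_support = max(.data$n_support), .groups = "drop") |>
    select("gene_id", "chrom", "start", "end", "strand", "tts",
           "n_support") |>
    arrange(.data$chrom, .data$start)
  structure(merged, class = c("rt_calls", class(tibble())))
}

#' Detect read-throughs for one genotype from per-replicate reads
#'
#' Convenience wrapper running the full per-genotype detection: subtract
#' annotated reads, build fragment-extended coverage, call intergenic peaks
#' in the strand-specific annotation complement, filter by TTS proximity and
#' take the replicate consensus.
#'
#' @param replicate_reads List of read tibbles, one per biological replicate.
#' @param ann A [genome_annotation()].
#' @param params A [peak_params()].
#' @param read_length Read length for the TTS-distance cutoff.
#' @param min_support Replicate consensus threshold.
#' @return An `rt_calls` tibble (see [replicate_consensus()]).
#' @export
detect_readthrough <- function(replicate_reads, ann, params = peak_params(),
                               read_length = 50L, min_support = 2L) {
  cs <- chrom_sizes_of(ann)
  regions <- bind_rows(strand_complement(ann, "+"),
                       strand_complement(ann, "-"))
  per_rep <- purrr::map(replicate_reads, function(reads) {
    kept <- subtract_annotated(reads, ann)
    cov <- coverage_from_reads(kept, cs, l_frag = params$l_frag)
    peaks <- call_peaks(cov, regions, params)
    filter_peaks_by_tts(peaks, ann, read_length = read_length)
  })
  replicate_consensus(per_rep, min_support = min_support, ann = ann)
}

#' Write read-through calls as GFF3 (feature type `readthrough`)
#'
#' @param calls An `rt_calls` tibble.
#' @param ann The [genome_annotation()] the calls were built against (for
#'   chromosome sizes).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_readthrough_gff3 <- function(calls, ann, path) {
  gr <- as_granges0(calls, chrom_sizes_of(ann))
  S4Vectors::mcols(gr)$ID <- paste0(calls$gene_id, "_RT")
  S4Vectors::mcols(gr)$Parent <- calls$gene_id
  S4Vectors::mcols(gr)$type <- "readthrough"
  S4Vectors::mcols(gr)$source <- "readthroughr"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
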