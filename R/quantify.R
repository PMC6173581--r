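#' Count fragments per feature by maximal same-strand overlap
#'
#' Reads are extended to `l_frag` fragments in their 3' direction and each
#' fragment is assigned to the same-strand feature with which it shares the
#' largest overlap. Ties go to the feature whose 5' end is nearest the
#' fragment's 5' end; fragments still tied, or overlapping no feature, are
#' counted in the `__unassigned__` audit row, so assigned plus unassigned
#' equals the total fragment count.
#'
#' @param reads Data frame with `chrom`, `start`, `end`, `strand`.
#' @param features Data frame with `feature_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param l_frag Fragment extension length (`NULL` to count raw reads).
#' @return Tibble with `feature_id` and `count`, one row per feature plus
#'   the `__unassigned__` row.
#' @export
count_fragments <- function(reads, features, chrom_sizes, l_frag = 363L) {
  assert_cols(features, c("feature_id", "chrom", "start", "end", "strand"),
              "features")
  frags <- extend_to_fragments(reads, chrom_sizes, l_frag)
  n_total <- nrow(frags)
  base <- tibble(feature_id = features$feature_id, count = 0L)
  if (n_total == 0) {
    return(bind_rows(base, tibble(feature_id = "__unassigned__", count = 0L)))
  }
  gr_f <- as_granges0(frags)
  gr_feat <- as_granges0(features)
  hits <- GenomicRanges::findOverlaps(gr_f, gr_feat, ignore.strand = FALSE)
  if (length(hits) == 0) {
    return(bind_rows(base,
                     tibble(feature_id = "__unassigned__", count = n_total)))
  }
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_f)[qi],
                                           IRanges::ranges(gr_feat)[si]))
  frag5 <- if_else(frags$strand == "+", frags$start, frags$end)[qi]
  feat5 <- if_else(features$strand == "+", features$start, features$end)[si]
  d5 <- abs(frag5 - feat5)
  ord <- order(qi, -ov, d5, si)
  qs <- qi[ord]; ovs <- ov[ord]; d5s <- d5[ord]; sis <- si[ord]
  is_best <- !duplicated(qs)
  # a fragment is ambiguous when its runner-up ties on both criteria
  nxt_same_frag <- c(qs[-1] == qs[-length(qs)], FALSE)
  tied <- is_best & nxt_same_frag &
    ovs == c(ovs[-1], NA) & d5s == c(d5s[-1], NA)
  keep <- is_best & !tied
  counts <- tabulate(sis[keep], nbins = nrow(features))
  bind_rows(tibble(feature_id = features$feature_id,
                   count = as.integer(counts)),
            tibble(feature_id = "__unassigned__",
                   count = n_total - sum(keep)))
}

# features table for "transcripts alone" and "transcripts + read-through"
features_from_annotation <- function(ann, rt_calls = NULL) {
  feats <- as_tibble(ann) |>
    mutate(feature_id = .data$gene_id) |>
    select("feature_id", "chrom", "start", "end", "strand")
  if (!is.null(rt_calls) && nrow(rt_calls) > 0) {
    rt <- as_tibble(rt_calls) |>
      mutate(feature_id = paste0(.data$gene_id, "_RT")) |>
      select("feature_id", "chrom", "start", "end", "strand")
    feats <- bind_rows(feats, rt)
  }
  feats
}

#' Build count tables for transcripts alone and transcripts plus read-through
#'
#' Quantification is performed twice, as in the source workflow: once on the
#' transcript annotation alone and once on the transcript annotation extended
#' with the merged read-through features, which appear as additional rows
#' named `<gene id>_RT`.
#'
#' @param reads Named list of per-sample read tibbles.
#' @param sample_sheet Tibble with `sample_id` (column order of the tables).
#' @param ann A [genome_annotation()].
#' @param rt_calls Merged read-through calls (may be empty/NULL, in which
#'   case both tables are identical).
#' @param l_frag Fragment extension length.
#' @return List with `transcripts` and `transcripts_rt`, each a tibble with
#'   `feature_id`, `length`, then one column per sample.
#' @export
build_count_tables <- function(reads, sample_sheet, ann, rt_calls = NULL,
                               l_frag = 363L) {
  if (!all(sample_sheet$sample_id %in% names(reads))) {
    abort("sample sheet lists samples absent from `reads`")
  }
  cs <- chrom_sizes_of(ann)
  one_table <- function(features) {
    cols <- purrr::map(sample_sheet$sample_id, function(s) {
      count_fragments(reads[[s]], features, cs, l_frag = l_frag) |>
        rename(!!s := "count")
    })
    tab <- purrr::reduce(cols, inner_join, by = "feature_id")
    lengths <- c(setNames(features$end - features$start,
                          features$feature_id),
                 "__unassigned__" = NA_integer_)
    mutate(tab, length = as.integer(lengths[.data$feature_id]),
           .after = "feature_id")
  }
  list(transcripts = one_table(features_from_annotation(ann)),
       transcripts_rt = one_table(features_from_annotation(ann, rt_calls)))
}

#' Write a count table as TSV
#'
#' @param counts A count tibble from [build_count_tables()].
#' @param path Output path.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(counts)
}
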