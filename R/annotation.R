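#' Build a genome annotation of transcription units
#'
#' A genome annotation is a tibble of single-interval transcription units
#' (no exon structure) together with chromosome sizes. It is the source of
#' transcription termination sites (TTS) and gene-orientation classes used by
#' the read-through detector.
#'
#' @param units Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`) and `biotype`. Coordinates are 0-based
#'   half-open.
#' @param chrom_sizes Named integer vector of chromosome lengths in bases.
#' @return A tibble of class `genome_annotation`, sorted by chromosome, start,
#'   end and id, with `chrom_sizes` stored as an attribute.
#' @examples
#' ann <- genome_annotation(
#'   tibble::tibble(gene_id = c("g1", "g2"), chrom = "I",
#'                  start = c(100, 700), end = c(500, 900),
#'                  strand = c("+", "-"), biotype = "mRNA"),
#'   chrom_sizes = c(I = 2000))
#' three_prime_end(ann)
#' @export
genome_annotation <- function(units, chrom_sizes) {
  assert_cols(units, c("gene_id", "chrom", "start", "end", "strand", "biotype"),
              "units")
  units <- as_tibble(units)
  assert_stranded(units, "transcription units")
  if (anyDuplicated(units$gene_id) > 0) {
    abort("transcription unit ids must be unique")
  }
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "")) {
    abort("`chrom_sizes` must be a named vector")
  }
  unknown <- setdiff(unique(units$chrom), names(chrom_sizes))
  if (length(unknown) > 0) {
    abort(sprintf("unknown chromosome(s) in annotation: %s",
                  paste(unknown, collapse = ", ")))
  }
  sz <- chrom_sizes[units$chrom]
  bad <- units$start < 0 | units$start >= units$end | units$end > sz
  if (any(bad)) {
    abort(sprintf(
      "%d unit(s) violate 0 <= start < end <= chromosome length (first: %s)",
      sum(bad), units$gene_id[which(bad)[1]]))
  }
  units <- arrange(units, .data$chrom, .data$start, .data$end, .data$gene_id)
  structure(units,
            chrom_sizes = chrom_sizes,
            class = c("genome_annotation", class(tibble())))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cs <- chrom_sizes_of(x)
  cat(sprintf("# Genome annotation: %d transcription units on %d chromosome(s)\n",
              nrow(x), length(cs)))
  NextMethod()
}

#' Read chromosome sizes from a two-column text file
#'
#' @param path Path to a tab-separated file with columns chromosome name and
#'   length (no header), as produced by `samtools faidx` cut to two columns.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "size"),
                        col_types = "ci", progress = FALSE)
  setNames(df$size, df$chrom)
}

# Default mapping from GFF3 feature type / biotype attribute to the package's
# biotype vocabulary.
default_biotype_map <- function() {
  c(gene = "mRNA", mRNA = "mRNA", protein_coding = "mRNA",
    ncRNA_gene = "ncRNA", ncRNA = "ncRNA",
    tRNA_gene = "tRNA", tRNA = "tRNA",
    rRNA_gene = "rRNA", rRNA = "rRNA",
    snRNA_gene = "snRNA", snRNA = "snRNA",
    snoRNA_gene = "snoRNA", snoRNA = "snoRNA",
    pseudogene = "other", pseudogenic_transcript = "other",
    other_gene = "other")
}

#' Read gene-level transcription units from a GFF3 file
#'
#' Imports gene-level features from a GFF3 annotation (1-based closed
#' coordinates) and converts them to the package's 0-based half-open
#' convention. Each retained feature becomes one single-interval transcription
#' unit; exon/CDS structure is ignored.
#'
#' @param path Path to a GFF3 file.
#' @param chrom_sizes Named vector of chromosome lengths. If `NULL`, lengths
#'   are taken from `##sequence-region` pragmas when present, otherwise from
#'   the right-most annotated coordinate per chromosome.
#' @param feature_types GFF3 `type` values treated as transcription units.
#'   The default covers gene-level features of every RNA class, so the unit
#'   count matches annotations in which ncRNA, tRNA, rRNA, sn(o)RNA genes are
#'   separate top-level types.
#' @param biotype_map Named character vector mapping GFF3 types (or Ensembl
#'   `biotype` attribute values) to biotypes; unmapped values become
#'   `"other"`.
#' @return A [genome_annotation()] tibble. The number of units read is
#'   reported with `message()`.
#' @export
read_gff3 <- function(path, chrom_sizes = NULL,
                      feature_types = names(default_biotype_map()),
                      biotype_map = default_biotype_map()) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 8)) {
    bad_line <- which(body)[which(nfield < 8)[1]]
    abort(sprintf("malformed GFF3 line %d in %s: fewer than 8 tab-separated fields",
                  bad_line, path))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  keep <- as.character(meta$type) %in% feature_types
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)

  id <- as.character(meta$ID)
  if (all(is.na(id)) || is.null(id)) id <- rep(NA_character_, length(gr))
  if ("Name" %in% names(meta)) {
    id <- ifelse(is.na(id), as.character(meta$Name), id)
  }
  if (anyNA(id)) {
    id[is.na(id)] <- sprintf("unit_%06d", which(is.na(id)))
  }

  src <- as.character(meta$type)
  if ("biotype" %in% names(meta)) {
    bt_attr <- as.character(meta$biotype)
    src <- ifelse(!is.na(bt_attr) & bt_attr %in% names(biotype_map), bt_attr, src)
  }
  biotype <- unname(biotype_map[src])
  biotype[is.na(biotype)] <- "other"

  units <- tibble(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = biotype
  )
  if (any(!units$strand %in% c("+", "-"))) {
    abort("GFF3 contains gene-level features without a definite strand")
  }
  if (is.null(chrom_sizes)) {
    region <- stringr::str_match(
      lines[startsWith(lines, "##sequence-region")],
      "^##sequence-region\\s+(\\S+)\\s+\\d+\\s+(\\d+)")
    region <- region[complete.cases(region), , drop = FALSE]
    if (nrow(region) > 0) {
      chrom_sizes <- setNames(as.integer(region[, 3]), region[, 2])
    } else {
      chrom_sizes <- tapply(units$end, units$chrom, max)
      chrom_sizes <- setNames(as.integer(chrom_sizes), names(chrom_sizes))
    }
  }
  ann <- genome_annotation(units, chrom_sizes)
  message(sprintf("read_gff3: %d transcription units from %s", nrow(ann), path))
  ann
}

#' Write / read transcription units or generic intervals as BED6
#'
#' BED is the package's native coordinate convention (0-based half-open), so
#' these are direct column mappings: name takes `gene_id` (or `name`), score
#' takes `score` when present (0 otherwise).
#'
#' @param x Data frame with `chrom`, `start`, `end`, `strand` and optionally
#'   `gene_id`/`name` and `score`.
#' @param path Output (input) file path.
#' @return `write_bed6()` returns `x` invisibly; `read_bed6()` returns a
#'   tibble with columns `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
write_bed6 <- function(x, path) {
  assert_cols(x, c("chrom", "start", "end", "strand"), "x")
  name <- if ("gene_id" %in% names(x)) x$gene_id
          else if ("name" %in% names(x)) x$name else "."
  score <- if ("score" %in% names(x)) x$score else 0
  out <- tibble(chrom = x$chrom, start = x$start, end = x$end,
                name = name, score = score, strand = x$strand)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(x)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "name", "score",
                                "strand"),
                  col_types = "ciicdc", progress = FALSE)
}

#' Strand-aware 3' ends (TTS) of transcription units
#'
#' The transcription termination site of a unit is its 3' boundary in the
#' half-open convention: `end` for `+` units (first base past the transcript)
#' and `start` for `-` units.
#'
#' @param ann A [genome_annotation()] (or any tibble with `start`, `end`,
#'   `strand`).
#' @return The input with a `tts` column appended.
#' @export
three_prime_end <- function(ann) {
  assert_cols(ann, c("start", "end", "strand"), "ann")
  assert_stranded(ann, "units")
  mutate(as_tibble(ann), tts = if_else(.data$strand == "+", .data$end, .data$start))
}

#' Strand-specific complement of an annotation
#'
#' Returns the maximal intervals of each chromosome not covered by any
#' transcription unit on the given strand — the gene-free regions in which
#' intergenic peaks are searched. Overlapping same-strand units are merged
#' before complementing, so complement plus merged annotation tiles each
#' chromosome exactly once.
#'
#' @param ann A [genome_annotation()].
#' @param strand `"+"` or `"-"`.
#' @return Tibble with `chrom`, `start`, `end`, `strand` (the queried strand).
#' @export
strand_complement <- function(ann, strand) {
  if (!strand %in% c("+", "-")) abort("`strand` must be '+' or '-'")
  cs <- chrom_sizes_of(ann)
  units <- filter(as_tibble(ann), .data$strand == !!strand)
  purrr::map_dfr(names(cs), function(chr) {
    len <- unname(cs[[chr]])
    u <- filter(units, .data$chrom == chr)
    if (nrow(u) == 0) {
      return(tibble(chrom = chr, start = 0L, end = as.integer(len)))
    }
    ir <- IRanges::reduce(IRanges::IRanges(u$start + 1L, u$end))
    gaps <- IRanges::gaps(ir, start = 1L, end = len)
    tibble(chrom = chr,
           start = IRanges::start(gaps) - 1L,
           end = IRanges::end(gaps))
  }) |>
    mutate(strand = !!strand) |>
    filter(.data$end > .data$start)
}

# Nearest downstream neighbour of every unit: the unit (either strand) past
# the query's 3' end in its direction of transcription, nearest by gap
# distance; overlap counts as gap 0. Ties broken by smaller start, then id.
nearest_downstream_neighbor <- function(ann) {
  units <- as_tibble(ann)
  units$.row <- seq_len(nrow(units))
  res <- purrr::map_dfr(split(units, units$chrom), function(u) {
    n <- nrow(u)
    u <- arrange(u, .data$start, .data$end, .data$gene_id)
    nb_id <- rep(NA_character_, n)
    nb_strand <- rep(NA_character_, n)
    nb_gap <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      g <- u[i, ]
      if (g$strand == "+") {
        cand <- u[u$end > g$end & u$gene_id != g$gene_id, ]
        if (nrow(cand) == 0) next
        gap <- pmax(0L, cand$start - g$end)
      } else {
        cand <- u[u$start < g$start & u$gene_id != g$gene_id, ]
        if (nrow(cand) == 0) next
        gap <- pmax(0L, g$start - cand$end)
      }
      ord <- order(gap, cand$start, cand$gene_id)
      best <- ord[1]
      nb_id[i] <- cand$gene_id[best]
      nb_strand[i] <- cand$strand[best]
      nb_gap[i] <- gap[best]
    }
    mutate(u, neighbor_id = nb_id, neighbor_strand = nb_strand,
           neighbor_gap = nb_gap)
  })
  arrange(res, .data$.row) |> select(-".row")
}

#' Classify transcription units by orientation relative to their downstream
#' neighbour
#'
#' Each unit is labelled by the strand of its nearest downstream neighbour
#' (the nearest unit, on either strand, past the unit's 3' end in its
#' direction of transcription; overlapping neighbours count with gap 0):
#' a neighbour on the opposite strand transcribes toward the unit, so their 3'
#' ends face — `convergent`; a same-strand neighbour is `tandem`; a unit with
#' no downstream neighbour on its chromosome is `isolated`. Under this
#' downstream-looking convention `divergent` (5' ends facing) never arises; the
#' level is kept in the factor so compositions always report all four classes.
#'
#' @param ann A [genome_annotation()].
#' @return The annotation tibble with columns `orientation` (factor with
#'   levels convergent, tandem, divergent, isolated), `neighbor_id` and
#'   `neighbor_gap` appended.
#' @export
classify_orientation <- function(ann) {
  if (nrow(ann) == 0) abort("annotation has no units")
  res <- nearest_downstream_neighbor(ann)
  lab <- dplyr::case_when(
    is.na(res$neighbor_strand) ~ "isolated",
    res$neighbor_strand == res$strand ~ "tandem",
    TRUE ~ "convergent"
  )
  mutate(res, orientation = factor(lab, levels = orientation_levels()))
}

orientation_levels <- function() c("convergent", "tandem", "divergent", "isolated")

#' Assign intervals to the nearest upstream TTS on the same strand
#'
#' For each stranded query interval (typically an intergenic peak), finds the
#' same-strand transcription unit whose TTS lies at or upstream of the
#' interval's 5' boundary (interval start on `+`, interval end on `-`) with
#' the minimal non-negative distance from TTS to that boundary.
#'
#' @param intervals Data frame with `chrom`, `start`, `end`, `strand`.
#' @param ann A [genome_annotation()].
#' @return `intervals` with `gene_id`, `tts` and `tts_distance` appended
#'   (`NA` where no same-strand unit lies upstream).
#' @export
nearest_tts_assignment <- function(intervals, ann) {
  assert_cols(intervals, c("chrom", "start", "end", "strand"), "intervals")
  assert_stranded(intervals, "intervals")
  units <- three_prime_end(ann)
  iv <- as_tibble(intervals)
  iv$.row <- seq_len(nrow(iv))
  out <- purrr::map_dfr(
    split(iv, list(iv$chrom, iv$strand), drop = TRUE),
    function(q) {
      chr <- q$chrom[1]; st <- q$strand[1]
      u <- filter(units, .data$chrom == chr, .data$strand == st) |>
        arrange(.data$tts, .data$gene_id)
      if (nrow(u) == 0) {
        return(mutate(q, gene_id = NA_character_, tts = NA_integer_,
                      tts_distance = NA_integer_))
      }
      bound <- if (st == "+") q$start else q$end
      if (st == "+") {
        # largest tts <= bound
        idx <- findInterval(bound, u$tts)
        hit <- idx >= 1
        idx[!hit] <- NA_integer_
      } else {
        # smallest tts >= bound
        idx <- findInterval(bound - 1L, u$tts) + 1L
        hit <- idx <= nrow(u)
        idx[!hit] <- NA_integer_
      }
      gene <- u$gene_id[idx]
      tts <- u$tts[idx]
      dist <- if (st == "+") bound - tts else tts - bound
      mutate(q, gene_id = gene, tts = as.integer(tts),
             tts_distance = as.integer(dist))
    })
  arrange(out, .data$.row) |> select(-".row")
}

#' Summarise an annotation: unit, biotype and orientation counts
#'
#' Reports the headline numbers a genome annotation yields under this
#' package's conventions: total transcription units, units per biotype, and
#' units per orientation class.
#'
#' @param ann A [genome_annotation()].
#' @return A list with `n_units`, a `biotype` count tibble and an
#'   `orientation` count tibble.
#' @export
annotation_summary <- function(ann) {
  ori <- classify_orientation(ann)
  list(
    n_units = nrow(ann),
    biotype = dplyr::count(as_tibble(ann), .data$biotype, name = "n"),
    orientation = dplyr::count(ori, .data$orientation, .drop = FALSE,
                               name = "n") |>
      mutate(fraction = .data$n / sum(.data$n))
  )
}
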