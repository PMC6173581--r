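test_that("GFF3 import converts 1-based closed to 0-based half-open and keeps ids/biotypes", {
  path <- withr::local_tempfile(fileext = ".gff3")
  write_toy_gff3(path)
  expect_message(ann <- read_gff3(path), "6 transcription units")
  expect_s3_class(ann, "genome_annotation")
  expect_equal(nrow(ann), 6)
  u <- toy_units()
  got <- dplyr::arrange(tibble::as_tibble(ann), gene_id)
  want <- dplyr::arrange(u, gene_id)
  # a feature written as start=101, end=600 must come back as [100, 600)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$strand, want$strand)
  expect_equal(got$biotype, want$biotype)
  expect_equal(unname(chrom_sizes_of(ann)["chrI"]), 4000)
})

test_that("malformed GFF3 lines are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chrI\tonly\tthree"), path)
  expect_error(read_gff3(path), "line 2")
})

test_that("annotation constructor enforces bounds, strands and unique ids", {
  u <- toy_units()
  expect_error(genome_annotation(u, c(chrI = 4000L)), "unknown chromosome")
  expect_error(
    genome_annotation(dplyr::mutate(u, strand = "."),
                      c(chrI = 4000L, chrII = 2500L)),
    "definite strand")
  expect_error(
    genome_annotation(dplyr::mutate(u, gene_id = "same"),
                      c(chrI = 4000L, chrII = 2500L)),
    "unique")
  expect_error(
    genome_annotation(dplyr::mutate(u, end = 10000L),
                      c(chrI = 4000L, chrII = 2500L)),
    "chromosome length")
})

test_that("three_prime_end returns end on + and start on - (half-open convention)", {
  ann <- toy_annotation()
  tts <- three_prime_end(ann)
  expect_equal(setNames(tts$tts, tts$gene_id)[names(toy_expected_tts)],
               toy_expected_tts)
  expect_error(three_prime_end(tibble::tibble(start = 1, end = 2, strand = ".")),
               "definite strand")
})

test_that("strand complement handles empty and single-gene annotations", {
  empty <- genome_annotation(
    tibble::tibble(gene_id = "g", chrom = "c", start = 100L, end = 200L,
                   strand = "+", biotype = "mRNA"),
    chrom_sizes = c(c = 1000L))
  plus <- strand_complement(empty, "+")
  expect_equal(plus$start, c(0L, 200L))
  expect_equal(plus$end, c(100L, 1000L))
  # the minus strand has no genes at all: one full-length interval
  minus <- strand_complement(empty, "-")
  expect_equal(minus$start, 0L)
  expect_equal(minus$end, 1000L)
})

test_that("strand complement matches a per-base oracle and tiles the chromosome", {
  for (seed in 1:3) {
    ann <- random_annotation(n_genes = 50, seed = seed)
    cs <- chrom_sizes_of(ann)
    for (st in c("+", "-")) {
      comp <- strand_complement(ann, st)
      for (chr in names(cs)) {
        got <- dplyr::filter(comp, chrom == chr)
        want <- oracle_complement(tibble::as_tibble(ann), cs[[chr]], chr, st)
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        # complement + merged annotation tiles the chromosome exactly once
        u <- dplyr::filter(tibble::as_tibble(ann), chrom == chr, strand == st)
        merged_len <- sum(IRanges::width(IRanges::reduce(
          IRanges::IRanges(u$start + 1, u$end))))
        expect_equal(sum(got$end - got$start) + merged_len, unname(cs[[chr]]))
      }
    }
  }
})

test_that("orientation of the toy annotation matches hand labels", {
  ori <- classify_orientation(toy_annotation())
  expect_equal(setNames(as.character(ori$orientation), ori$gene_id)[
    names(toy_expected_orientation)],
    toy_expected_orientation)
})

test_that("orientation matches the exhaustive pairwise oracle on random annotations", {
  for (seed in 4:6) {
    ann <- random_annotation(n_genes = 20, seed = seed)
    got <- classify_orientation(ann)
    expect_equal(as.character(got$orientation), unname(oracle_orientation(ann)))
  }
})

test_that("orientation labels survive reverse-complementing the genome", {
  ann <- random_annotation(n_genes = 30, seed = 11)
  cs <- chrom_sizes_of(ann)
  flipped <- genome_annotation(
    dplyr::mutate(tibble::as_tibble(ann),
                  new_start = unname(cs[chrom]) - end,
                  new_end = unname(cs[chrom]) - start,
                  start = as.integer(new_start), end = as.integer(new_end),
                  strand = ifelse(strand == "+", "-", "+")) |>
      dplyr::select(-new_start, -new_end),
    chrom_sizes = cs)
  ori <- classify_orientation(ann)
  ori_flipped <- classify_orientation(flipped)
  lab <- setNames(as.character(ori$orientation), ori$gene_id)
  lab_f <- setNames(as.character(ori_flipped$orientation), ori_flipped$gene_id)
  expect_equal(lab_f[names(lab)], lab)
})

test_that("nearest TTS assignment: boundary conventions and exhaustive oracle", {
  ann <- toy_annotation()
  # peak starting exactly at tA's TTS -> distance 0
  iv0 <- tibble::tibble(chrom = "chrI", start = 600L, end = 700L, strand = "+")
  got0 <- nearest_tts_assignment(iv0, ann)
  expect_equal(got0$gene_id, "tA")
  expect_equal(got0$tts_distance, 0L)
  # + peak 80 bases past the TTS
  iv80 <- tibble::tibble(chrom = "chrI", start = 680L, end = 780L, strand = "+")
  expect_equal(nearest_tts_assignment(iv80, ann)$tts_distance, 80L)
  # - strand: boundary is the interval end
  ivm <- tibble::tibble(chrom = "chrI", start = 1500L, end = 1560L, strand = "-")
  gotm <- nearest_tts_assignment(ivm, ann)
  expect_equal(gotm$gene_id, "tC")
  expect_equal(gotm$tts_distance, 40L)

  set.seed(42)
  rann <- random_annotation(n_genes = 15, seed = 7)
  ivs <- random_stranded_intervals(30, chrom_sizes_of(rann))
  got <- nearest_tts_assignment(ivs, rann)
  for (i in seq_len(nrow(ivs))) {
    want <- oracle_nearest_tts(ivs[i, ], rann)
    if (is.null(want)) {
      expect_true(is.na(got$gene_id[i]))
    } else {
      expect_equal(got$tts_distance[i], as.integer(want$distance))
      expect_equal(want$distance >= 0, TRUE)
    }
  }
})

test_that("BED6 round-trip preserves intervals", {
  ann <- toy_annotation()
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed6(ann, path)
  back <- read_bed6(path)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$strand, ann$strand)
  expect_equal(back$name, ann$gene_id)
})

test_that("annotation summary reports unit, biotype and orientation counts", {
  s <- annotation_summary(toy_annotation())
  expect_equal(s$n_units, 6)
  expect_equal(s$biotype$n[s$biotype$biotype == "mRNA"], 4)
  ori <- setNames(s$orientation$n, as.character(s$orientation$orientation))
  expect_equal(unname(ori["convergent"]), 2)
  expect_equal(unname(ori["tandem"]), 2)
  expect_equal(unname(ori["isolated"]), 2)
  expect_equal(sum(s$orientation$fraction), 1)
})
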