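test_that("annotated-read subtraction is strand-specific and conserves reads", {
  ann <- toy_annotation()
  reads <- tibble::tibble(
    chrom = c("chrI", "chrI", "chrI"),
    start = c(200L, 200L, 3200L),
    end = c(250L, 250L, 3250L),
    strand = c("+", "-", "+"))
  kept <- subtract_annotated(reads, ann)
  # inside tA on the same strand -> removed; antisense -> kept;
  # intergenic -> kept
  expect_equal(nrow(kept), 2)
  expect_equal(kept$strand, c("-", "+"))

  set.seed(5)
  rann <- random_annotation(n_genes = 30, seed = 3)
  rr <- random_stranded_intervals(500, chrom_sizes_of(rann),
                                  width_range = c(50, 50))
  kept <- subtract_annotated(rr, rann)
  overlap_any <- sapply(seq_len(nrow(rr)), function(i) {
    u <- dplyr::filter(tibble::as_tibble(rann), chrom == rr$chrom[i],
                       strand == rr$strand[i])
    any(u$start < rr$end[i] & u$end > rr$start[i])
  })
  expect_equal(nrow(kept) + sum(overlap_any), nrow(rr))
  expect_equal(kept, rr[!overlap_any, ])
})

test_that("TTS filter keeps peaks at <= 2 read lengths and drops beyond", {
  ann <- toy_annotation()
  peaks <- tibble::tibble(
    chrom = "chrI",
    start = c(700L, 701L, 600L),
    end = c(760L, 761L, 660L),
    strand = "+",
    score = 1)
  kept <- filter_peaks_by_tts(peaks, ann, read_length = 50L)
  # 100 past tA's TTS kept (inclusive boundary), 101 dropped, 0 kept
  expect_equal(kept$start, c(700L, 600L))
  expect_equal(kept$gene_id, c("tA", "tA"))
  expect_equal(kept$tts_distance, c(100L, 0L))
})

test_that("TTS filter matches a hand-filtered list and truncates at downstream genes", {
  ann <- toy_annotation()
  peaks <- tibble::tibble(
    chrom  = c("chrI", "chrI", "chrI", "chrI",  "chrI", "chrI", "chrII",
               "chrII", "chrI", "chrI"),
    start  = c(610L,  750L,   1450L,  1480L,   2280L,  3100L,  50L,
               1900L, 640L,  1405L),
    end    = c(700L,  820L,   1530L,  1700L,   2400L,  3200L,  160L,
               2000L, 690L,  1500L),
    strand = c("+",   "+",    "-",    "+",     "-",    "-",    "-",
               "+",   "-",   "+"),
    score = 1)
  kept <- filter_peaks_by_tts(peaks, ann, read_length = 50L)
  # hand application of the rule:
  # 1 (+,610-700): tA TTS 600, dist 10 -> keep
  # 2 (+,750-820): dist 150 -> drop
  # 3 (-,1450-1530): tC TTS 1600, dist 70 -> keep
  # 4 (+,1480-1700): tB TTS 1400, dist 80 -> keep, truncated at tC? same
  #    strand only: tC is -, no truncation
  # 5 (-,2280-2400): tD TTS 2500, dist 100 -> keep
  # 6 (-,3100-3200): no - TTS at/above 3200 on chrI... tD TTS 2500 < 3200 ->
  #    no upstream TTS on the minus strand -> drop
  # 7 (chrII,-,50-160): tE TTS 200, dist 40 -> keep
  # 8 (chrII,+,1900-2000): tF TTS 1800, dist 100 -> keep
  # 9 (-,640-690): nearest - TTS >= 690 is tC 1600, dist 910 -> drop
  # 10 (+,1405-1500): tB dist 5 -> keep
  expect_equal(kept$gene_id, c("tA", "tC", "tB", "tD", "tE", "tF", "tB"))
  expect_equal(kept$tts_distance, c(10L, 70L, 80L, 100L, 40L, 100L, 5L))
})

test_that("peaks reaching into a downstream same-strand gene are truncated or dropped", {
  ann <- toy_annotation()
  # + peak past tA's TTS running into tB [800,1400)
  peaks <- tibble::tibble(chrom = "chrI", start = 650L, end = 1000L,
                          strand = "+", score = 1)
  kept <- filter_peaks_by_tts(peaks, ann, read_length = 50L)
  expect_equal(kept$end, 800L)
  # peak fully inside a same-strand gene is dropped
  inside <- tibble::tibble(chrom = "chrI", start = 900L, end = 1000L,
                           strand = "+", score = 1)
  expect_equal(nrow(readthroughr:::truncate_at_downstream_gene(inside, ann)), 0)
})

test_that("replicate consensus applies the 2-of-3 rule and the median boundary", {
  ann <- toy_annotation()
  call_at <- function(far) {
    tibble::tibble(chrom = "chrI", start = 600L, end = far, strand = "+",
                   score = 1, gene_id = "tA", tts = 600L, tts_distance = 0L)
  }
  reps <- list(call_at(700L), call_at(750L),
               tibble::tibble(chrom = character(), start = integer(),
                              end = integer(), strand = character(),
                              score = double(), gene_id = character(),
                              tts = integer(), tts_distance = integer()))
  cons <- replicate_consensus(reps, min_support = 2L, ann = ann)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$gene_id, "tA")
  expect_equal(cons$start, 600L)  # extension begins exactly at the TTS
  expect_equal(cons$n_support, 2L)
  # 1 of 3 -> dropped
  cons1 <- replicate_consensus(list(call_at(700L), reps[[3]], reps[[3]]),
                               min_support = 2L, ann = ann)
  expect_equal(nrow(cons1), 0)
  # median of 400/450/500 past the TTS
  cons3 <- replicate_consensus(list(call_at(1000L), call_at(1050L),
                                    call_at(1100L)), min_support = 2L)
  expect_equal(cons3$end, 1050L)
  expect_error(replicate_consensus(reps, min_support = 4L), "min_support")
})

test_that("raising min_support never increases the number of consensus calls", {
  cfg <- sim_config(n_genes = 60L, n_chroms = 1L, chrom_length = 150000L,
                    seed = 31, rt_fraction = 0.3)
  sim <- simulate_dataset(cfg)
  ann <- sim$annotation
  regions <- dplyr::bind_rows(strand_complement(ann, "+"),
                              strand_complement(ann, "-"))
  per_rep <- purrr::map(sim$sample_sheet$sample_id[
    sim$sample_sheet$genotype == "cut14"], function(s) {
      kept <- subtract_annotated(sim$reads[[s]], ann)
      cov <- coverage_from_reads(kept, chrom_sizes_of(ann), l_frag = 363L)
      filter_peaks_by_tts(call_peaks(cov, regions), ann)
    })
  n <- sapply(1:3, function(ms)
    nrow(replicate_consensus(per_rep, min_support = ms, ann = ann)))
  expect_true(all(diff(n) <= 0))
  # every consensus extension starts at its gene's TTS with positive length
  cons <- replicate_consensus(per_rep, min_support = 2L, ann = ann)
  tts <- setNames(three_prime_end(ann)$tts, ann$gene_id)
  plus <- dplyr::filter(cons, strand == "+")
  minus <- dplyr::filter(cons, strand == "-")
  expect_equal(plus$start, unname(tts[plus$gene_id]))
  expect_equal(minus$end, unname(tts[minus$gene_id]))
  expect_true(all(cons$end > cons$start))
})

test_that("genotype merges take the union span and reject annotation conflicts", {
  a <- structure(tibble::tibble(
    gene_id = c("g1", "g2"), chrom = "c", start = c(100L, 500L),
    end = c(200L, 600L), strand = "+", tts = c(100L, 500L),
    n_support = 2L), class = c("rt_calls", class(tibble::tibble())))
  b <- structure(tibble::tibble(
    gene_id = c("g2", "g3"), chrom = "c", start = c(500L, 900L),
    end = c(700L, 950L), strand = "+", tts = c(500L, 900L),
    n_support = 3L), class = c("rt_calls", class(tibble::tibble())))
  m <- merge_genotype_annotations(a, b)
  expect_equal(nrow(m), 3)
  expect_lte(nrow(m), nrow(a) + nrow(b))
  g2 <- dplyr::filter(m, gene_id == "g2")
  expect_equal(g2$end, 700L)  # union span: boundaries 100 and 200 past TTS
  # disjoint sets -> simple union
  expect_equal(sort(m$gene_id), c("g1", "g2", "g3"))
  # same gene anchored at a different TTS -> conflicting annotations
  b_bad <- dplyr::mutate(b, tts = ifelse(gene_id == "g2", 450L, tts))
  expect_error(merge_genotype_annotations(a, b_bad), "inconsistent")
})
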