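# Shared fixtures: a small hand-checkable annotation, a GFF3 writer for it,
# and random annotations for property tests.

toy_units <- function() {
  tibble::tribble(
    ~gene_id, ~chrom,  ~start, ~end,  ~strand, ~biotype,
    "tA",     "chrI",   100L,   600L,  "+",     "mRNA",   # tandem with tB
    "tB",     "chrI",   800L,  1400L,  "+",     "mRNA",   # convergent with tC
    "tC",     "chrI",  1600L,  2200L,  "-",     "ncRNA",  # convergent with tB
    "tD",     "chrI",  2500L,  3000L,  "-",     "mRNA",   # downstream nb = tC
    "tE",     "chrII",  200L,   900L,  "-",     "snoRNA", # no downstream nb
    "tF",     "chrII", 1200L,  1800L,  "+",     "mRNA"    # no downstream nb
  )
}

toy_annotation <- function() {
  genome_annotation(toy_units(), chrom_sizes = c(chrI = 4000L, chrII = 2500L))
}

# hand-derived facts about the toy annotation
toy_expected_tts <- c(tA = 600L, tB = 1400L, tC = 1600L, tD = 2500L,
                      tE = 200L, tF = 1800L)
toy_expected_orientation <- c(
  tA = "tandem",      # nearest downstream is tB (+)
  tB = "convergent",  # nearest downstream is tC (-)
  tC = "convergent",  # transcribes leftward; nearest is tB (+)
  tD = "tandem",      # transcribes leftward; nearest is tC (-)
  tE = "isolated",    # nothing left of it on chrII
  tF = "isolated"     # nothing right of it on chrII
)

write_toy_gff3 <- function(path) {
  u <- toy_units()
  type <- ifelse(u$biotype == "mRNA", "gene", paste0(u$biotype, "_gene"))
  lines <- c(
    "##gff-version 3",
    "##sequence-region chrI 1 4000",
    "##sequence-region chrII 1 2500",
    sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
            u$chrom, type, u$start + 1L, u$end, u$strand, u$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}

random_annotation <- function(n_genes = 50, seed = 1, n_chroms = 2,
                              chrom_length = 60000) {
  generate_annotation(sim_config(
    n_genes = n_genes, n_chroms = n_chroms, chrom_length = chrom_length,
    gene_length_meanlog = log(600), gene_length_sdlog = 0.5,
    intergap_min = 20L, intergap_mean = 300, seed = seed))
}

random_stranded_intervals <- function(n, chrom_sizes, width_range = c(50, 500)) {
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  start <- floor(runif(n, 0, unname(chrom_sizes[chrom]) - w))
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(start + w),
                 strand = sample(c("+", "-"), n, replace = TRUE))
}
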