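#' Configuration for the stranded RNA-seq simulator
#'
#' Defaults emulate the design of a fission-yeast condensin/exosome
#' transcriptome experiment: three biological replicates per genotype
#' (wild type plus two mutants), single-end 50 nt reads from fragments of
#' mean length 363.4 (sd 85.53354), negative-binomial gene-level counts, a
#' ~22% ncRNA annotation, a subset of genes with planted 3' read-through
#' tails in the mutants, and a subset with true up/down fold changes.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bases).
#' @param n_genes Number of transcription units to place.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene length
#'   parameters (bases).
#' @param intergap_min,intergap_mean Minimal and mean intergenic gap; gaps are
#'   `intergap_min` plus an exponential draw.
#' @param biotype_fractions Named fractions per biotype (must sum to 1);
#'   default 22% ncRNA.
#' @param read_length Read length in nt.
#' @param frag_mean,frag_sd Fragment length distribution (normal, truncated
#'   below at `read_length`).
#' @param genotypes Character vector; the first entry is the reference
#'   (wild type), the rest are mutants.
#' @param replicates Biological replicates per genotype.
#' @param mu_meanlog,mu_sdlog Log-normal parameters of per-gene baseline mean
#'   fragment counts.
#' @param dispersion Negative-binomial dispersion alpha (var = mu + alpha mu^2).
#' @param de_fraction Fraction of genes with a true fold change in each
#'   mutant.
#' @param de_lfc Absolute true log2 fold change of DE genes.
#' @param de_up_fraction Fraction of DE genes that go up (the rest go down).
#' @param rt_fraction Fraction of genes with a planted read-through in each
#'   mutant.
#' @param rt_read_fraction Fraction of a read-through gene's fragments drawn
#'   from the 3' extension rather than the gene body.
#' @param rt_ext_mean Mean of the (truncated) geometric extension length in
#'   nt; per-fragment offsets past the TTS decay geometrically with the same
#'   mean, so extension coverage decays 3' of the TTS.
#' @param noise_rate Background fragments (uniform over the genome, both
#'   strands) as a fraction of a sample's real fragments.
#' @param sf_sdlog Log-normal sd of per-sample library size factors.
#' @param seed Integer seed; a fixed seed makes the whole dataset
#'   reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L,
                       chrom_length = 200000L,
                       n_genes = 200L,
                       gene_length_meanlog = log(1200),
                       gene_length_sdlog = 0.4,
                       intergap_min = 60L,
                       intergap_mean = 400,
                       biotype_fractions = c(mRNA = 0.78, ncRNA = 0.22),
                       read_length = 50L,
                       frag_mean = 363.4,
                       frag_sd = 85.53354,
                       genotypes = c("wt", "cut14", "rrp6"),
                       replicates = 3L,
                       mu_meanlog = log(150),
                       mu_sdlog = 1,
                       dispersion = 0.05,
                       de_fraction = 0.1,
                       de_lfc = 1,
                       de_up_fraction = 0.8,
                       rt_fraction = 0.1,
                       rt_read_fraction = 0.5,
                       rt_ext_mean = 300,
                       noise_rate = 0.01,
                       sf_sdlog = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  fr <- unlist(cfg$biotype_fractions)
  if (abs(sum(fr) - 1) > 1e-8 || any(fr < 0)) {
    abort("`biotype_fractions` must be non-negative and sum to 1")
  }
  for (f in c("de_fraction", "de_up_fraction", "rt_fraction",
              "rt_read_fraction", "noise_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(sprintf("`%s` must be in [0, 1]", f))
  }
  if (cfg$read_length >= cfg$frag_mean) {
    abort("`read_length` must be smaller than the mean fragment length")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a random non-overlapping gene annotation
#'
#' Genes are laid left to right with log-normal lengths and exponential
#' intergenic gaps (minimum `intergap_min`), random strands and biotypes, and
#' moved to the next chromosome when the current one is full.
#'
#' @param cfg A [sim_config()].
#' @return A [genome_annotation()].
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "annotation"))
  chroms <- sprintf("chr%s", utils::as.roman(seq_len(cfg$n_chroms)))
  cs <- setNames(rep(as.integer(cfg$chrom_length), cfg$n_chroms), chroms)
  lens <- pmax(cfg$read_length * 2L,
               as.integer(round(rlnorm(cfg$n_genes, cfg$gene_length_meanlog,
                                       cfg$gene_length_sdlog))))
  gaps <- as.integer(cfg$intergap_min +
                       round(stats::rexp(cfg$n_genes, 1 / cfg$intergap_mean)))
  strands <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  biotypes <- sample(names(cfg$biotype_fractions), cfg$n_genes, replace = TRUE,
                     prob = cfg$biotype_fractions)
  chrom <- character(cfg$n_genes)
  start <- integer(cfg$n_genes)
  ci <- 1L
  pos <- gaps[1]
  for (i in seq_len(cfg$n_genes)) {
    if (pos + lens[i] + cfg$intergap_min > cfg$chrom_length) {
      ci <- ci + 1L
      if (ci > cfg$n_chroms) {
        abort("infeasible packing: genes do not fit the configured chromosomes")
      }
      pos <- gaps[i]
    }
    chrom[i] <- chroms[ci]
    start[i] <- pos
    pos <- pos + lens[i] + gaps[i]
  }
  genome_annotation(
    tibble(gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
           chrom = chrom, start = start, end = start + lens,
           strand = strands, biotype = biotypes),
    chrom_sizes = cs)
}

# gap from each gene's TTS to the next same-strand unit (or chromosome end)
same_strand_downstream_gap <- function(ann) {
  cs <- chrom_sizes_of(ann)
  units <- three_prime_end(ann)
  purrr::map_dbl(seq_len(nrow(units)), function(i) {
    g <- units[i, ]
    u <- units[units$chrom == g$chrom & units$strand == g$strand &
                 units$gene_id != g$gene_id, ]
    if (g$strand == "+") {
      nxt <- u$start[u$start >= g$tts]
      lim <- if (length(nxt) > 0) min(nxt) else unname(cs[[g$chrom]])
      lim - g$tts
    } else {
      nxt <- u$end[u$end <= g$tts]
      lim <- if (length(nxt) > 0) max(nxt) else 0
      g$tts - lim
    }
  })
}

#' Draw the simulation ground truth
#'
#' Per gene and genotype: baseline mean, true log2 fold change, read-through
#' status and planted extension length. Extensions are truncated-geometric
#' draws capped so that no extension crosses into the next same-strand gene
#' (or off the chromosome).
#'
#' @param ann A [genome_annotation()] (typically from
#'   [generate_annotation()]).
#' @param cfg A [sim_config()].
#' @return Tibble of class `sim_truth`: one row per gene x genotype with
#'   `mu`, `lfc`, `is_readthrough`, `ext_length` (NA when not read-through),
#'   plus per-sample size factors in the `size_factors` attribute.
#' @export
simulate_truth <- function(ann, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "truth"))
  n <- nrow(ann)
  mu <- rlnorm(n, cfg$mu_meanlog, cfg$mu_sdlog)
  gap <- same_strand_downstream_gap(ann)
  mutants <- setdiff(cfg$genotypes, cfg$genotypes[1])
  per_geno <- purrr::map_dfr(cfg$genotypes, function(g) {
    if (g == cfg$genotypes[1]) {
      return(tibble(gene_id = ann$gene_id, genotype = g, lfc = 0,
                    is_readthrough = FALSE, ext_length = NA_integer_))
    }
    n_de <- round(cfg$de_fraction * n)
    de_genes <- sample(ann$gene_id, n_de)
    sgn <- ifelse(runif(n_de) < cfg$de_up_fraction, 1, -1)
    lfc <- setNames(rep(0, n), ann$gene_id)
    lfc[de_genes] <- sgn * cfg$de_lfc
    n_rt <- round(cfg$rt_fraction * n)
    rt_genes <- sample(ann$gene_id, n_rt)
    is_rt <- ann$gene_id %in% rt_genes
    ext <- rep(NA_integer_, n)
    cap <- pmax(1L, as.integer(gap) - 1L)
    draw <- 1L + rgeom(n, 1 / cfg$rt_ext_mean)
    ext[is_rt] <- pmin(draw, cap)[is_rt]
    tibble(gene_id = ann$gene_id, genotype = g, lfc = unname(lfc),
           is_readthrough = is_rt, ext_length = ext)
  })
  truth <- inner_join(
    tibble(gene_id = ann$gene_id, mu = mu),
    per_geno, by = "gene_id") |>
    arrange(match(.data$genotype, cfg$genotypes), .data$gene_id)
  samples <- tidyr::expand_grid(genotype = cfg$genotypes,
                                replicate = seq_len(cfg$replicates)) |>
    mutate(sample_id = sprintf("%s_rep%d", .data$genotype, .data$replicate),
           size_factor = rlnorm(dplyr::n(), 0, cfg$sf_sdlog))
  structure(truth, sample_sheet = samples,
            class = c("sim_truth", class(tibble())))
}

# truncated geometric fragment offsets past the TTS (0-based, decaying)
rgeom_trunc <- function(n, mean, cap) {
  x <- rgeom(n, 1 / mean)
  over <- x > cap
  while (any(over)) {
    x[over] <- rgeom(sum(over), 1 / mean)
    over <- x > cap
  }
  x
}

#' Simulate one stranded sample
#'
#' Draws per-gene fragment counts from a negative binomial with mean
#' `size_factor * mu * 2^lfc` and dispersion `cfg$dispersion`, places gene-body
#' fragments uniformly within the transcript, and for read-through genes draws
#' a `rt_read_fraction` share of fragments whose 5' ends start past the TTS at
#' geometrically decaying offsets within the planted extension. Reads are the
#' first `read_length` bases of each fragment on the gene's strand. Uniform
#' background fragments on both strands model spurious signal.
#'
#' @param ann A [genome_annotation()].
#' @param truth A [simulate_truth()] result.
#' @param genotype,replicate Which sample to draw.
#' @param cfg A [sim_config()].
#' @return Tibble of reads: `chrom`, `start`, `end`, `strand`, `origin`
#'   (gene id, `<gene>_RT` for extension reads, or `noise`).
#' @export
simulate_sample <- function(ann, truth, genotype, replicate, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sheet <- attr(truth, "sample_sheet", exact = TRUE)
  row <- filter(sheet, .data$genotype == !!genotype,
                .data$replicate == !!replicate)
  if (nrow(row) != 1) abort("unknown genotype/replicate combination")
  set.seed(derive_seed(cfg$seed, paste0("sample_", row$sample_id)))
  cs <- chrom_sizes_of(ann)
  units <- three_prime_end(ann)
  tt <- filter(as_tibble(truth), .data$genotype == !!genotype) |>
    inner_join(select(units, "gene_id", "chrom", "start", "end", "strand",
                      "tts"),
               by = "gene_id")
  mean_counts <- row$size_factor * tt$mu * 2^tt$lfc
  k_body <- rnbinom(nrow(tt), mu = mean_counts, size = 1 / cfg$dispersion)
  # extension fragments are supplementary: a read-through RNA still carries
  # the full gene body, so planting a tail must not deplete body coverage
  k_rt <- ifelse(tt$is_readthrough,
                 rbinom(nrow(tt), k_body, cfg$rt_read_fraction), 0L)

  frag_len <- function(n) {
    pmax(cfg$read_length,
         as.integer(round(rnorm(n, cfg$frag_mean, cfg$frag_sd))))
  }

  make_body <- function(i) {
    n <- k_body[i]
    if (n == 0) return(NULL)
    g <- tt[i, ]
    glen <- g$end - g$start
    fl <- pmin(frag_len(n), glen)
    off <- floor(runif(n, 0, glen - fl + 1))
    if (g$strand == "+") {
      fs <- g$start + off
    } else {
      fs <- g$end - off - fl
    }
    tibble(chrom = g$chrom, fstart = as.integer(fs),
           fend = as.integer(fs + fl), strand = g$strand, origin = g$gene_id)
  }
  make_rt <- function(i) {
    n <- k_rt[i]
    if (n == 0) return(NULL)
    g <- tt[i, ]
    cap <- max(0L, g$ext_length - cfg$read_length)
    e <- rgeom_trunc(n, cfg$rt_ext_mean, cap)
    fl <- frag_len(n)
    if (g$strand == "+") {
      fs <- g$tts + e
      fe <- pmin(fs + fl, g$tts + g$ext_length)
    } else {
      fe <- g$tts - e
      fs <- pmax(fe - fl, g$tts - g$ext_length)
    }
    tibble(chrom = g$chrom, fstart = as.integer(fs), fend = as.integer(fe),
           strand = g$strand, origin = paste0(g$gene_id, "_RT"))
  }
  frags <- bind_rows(purrr::map(seq_len(nrow(tt)), make_body),
                     purrr::map(seq_len(nrow(tt)), make_rt))

  n_noise <- rpois(1, cfg$noise_rate * nrow(frags))
  if (n_noise > 0) {
    chr <- sample(names(cs), n_noise, replace = TRUE)
    fl <- frag_len(n_noise)
    fs <- floor(runif(n_noise, 0, unname(cs[chr]) - fl))
    frags <- bind_rows(frags,
                       tibble(chrom = chr, fstart = as.integer(fs),
                              fend = as.integer(fs + fl),
                              strand = sample(c("+", "-"), n_noise,
                                              replace = TRUE),
                              origin = "noise"))
  }
  if (nrow(frags) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), origin = character()))
  }
  # read = first read_length bases of the fragment (5' end), clipped to bounds
  frags <- mutate(frags,
    start = if_else(.data$strand == "+", .data$fstart,
                    pmax(.data$fstart, .data$fend - cfg$read_length)),
    end = if_else(.data$strand == "+",
                  pmin(.data$fend, .data$fstart + cfg$read_length),
                  .data$fend),
    start = pmax(.data$start, 0L),
    end = pmin(.data$end, unname(cs[.data$chrom])))
  frags |>
    filter(.data$end > .data$start) |>
    select("chrom", "start", "end", "strand", "origin") |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand)
}

#' Simulate a complete multi-genotype dataset
#'
#' @param cfg A [sim_config()].
#' @return List of class `rt_sim`: `annotation`, `truth`, `sample_sheet`,
#'   `reads` (named list of per-sample read tibbles) and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  ann <- generate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  sheet <- attr(truth, "sample_sheet", exact = TRUE)
  reads <- purrr::map2(sheet$genotype, sheet$replicate,
                       \(g, r) simulate_sample(ann, truth, g, r, cfg))
  names(reads) <- sheet$sample_id
  structure(list(annotation = ann, truth = truth, sample_sheet = sheet,
                 reads = reads, config = cfg),
            class = "rt_sim")
}

#' @export
print.rt_sim <- function(x, ...) {
  cat(sprintf(
    "# Simulated stranded RNA-seq dataset: %d genes, %d samples (%s), seed %d\n",
    nrow(x$annotation), length(x$reads),
    paste(unique(x$sample_sheet$genotype), collapse = "/"),
    x$config$seed))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits per-sample BED6 reads, per-sample per-strand bedGraph coverage of the
#' raw reads, the annotation as GFF3, the truth table and sample sheet as TSV,
#' chromosome sizes, and the configuration as JSON.
#'
#' @param sim An [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "rt_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cs <- chrom_sizes_of(sim$annotation)
  write_gff3_units(sim$annotation, file.path(dir, "annotation.gff3"))
  readr::write_tsv(tibble(chrom = names(cs), size = unname(cs)),
                   file.path(dir, "chrom.sizes"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(as_tibble(sim$truth), file.path(dir, "truth.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$sample_sheet, file.path(dir, "samples.tsv"),
                   progress = FALSE)
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  for (s in names(sim$reads)) {
    reads <- rename(sim$reads[[s]], name = "origin")
    write_bed6(reads, file.path(dir, paste0(s, ".bed")))
    cov <- coverage_from_reads(reads, cs, l_frag = NULL)
    for (st in c("+", "-")) {
      tag <- if (st == "+") "fwd" else "rev"
      write_bedgraph(filter(cov, .data$strand == st),
                     file.path(dir, sprintf("%s.%s.bedgraph", s, tag)))
    }
  }
  invisible(dir)
}

# annotation -> GFF3 (1-based closed) via rtracklayer
write_gff3_units <- function(ann, path, feature_type = NULL) {
  gr <- as_granges0(ann, chrom_sizes_of(ann))
  S4Vectors::mcols(gr)$ID <- ann$gene_id
  S4Vectors::mcols(gr)$type <- feature_type %||% paste0(ann$biotype, "_gene") |>
    stringr::str_replace("^mRNA_gene$", "gene")
  S4Vectors::mcols(gr)$source <- "readthroughr"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a simulated (or external) dataset back from disk
#'
#' Counterpart of [write_dataset()]: loads annotation, sample sheet and
#' per-sample reads.
#'
#' @param dir Directory written by [write_dataset()].
#' @return List with `annotation`, `sample_sheet`, `reads` and `truth` (NULL
#'   when absent).
#' @export
read_dataset <- function(dir) {
  cs <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  ann <- suppressMessages(
    read_gff3(file.path(dir, "annotation.gff3"), chrom_sizes = cs))
  sheet <- readr::read_tsv(file.path(dir, "samples.tsv"),
                           col_types = readr::cols(), progress = FALSE)
  reads <- purrr::map(sheet$sample_id, function(s) {
    read_bed6(file.path(dir, paste0(s, ".bed"))) |>
      rename(origin = "name") |>
      select("chrom", "start", "end", "strand", "origin")
  })
  names(reads) <- sheet$sample_id
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    readr::read_tsv(truth_path, col_types = readr::cols(), progress = FALSE)
  }
  list(annotation = ann, sample_sheet = sheet, reads = reads, truth = truth)
}
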