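#' Configuration for the end-to-end pipeline
#'
#' Bundles the per-module parameters with their standard defaults: 50 nt
#' reads (so the TTS-distance cutoff is two read lengths = 100 bases),
#' replicate consensus of 2, DE thresholds log2FC 0.5 at FDR 0.05, one-sided
#' read-through presence test at log2FC 0, and the peak-scan parameters of
#' [peak_params()].
#'
#' @param sim A [sim_config()] to simulate input data, or `NULL` when
#'   `data_dir` provides real inputs.
#' @param data_dir Directory with `annotation.gff3`, `chrom.sizes`,
#'   `samples.tsv` and per-sample BED reads (see [read_dataset()]); ignored
#'   when `sim` is given.
#' @param contrasts List of character pairs `c(mutant, reference)`; `NULL`
#'   tests every non-reference genotype against the first genotype.
#' @param peak A [peak_params()] list.
#' @param read_length Read length (TTS filter = 2x this).
#' @param min_support Replicate-consensus threshold.
#' @param lfc,alpha DE fold-change threshold and FDR level.
#' @param quant_l_frag Fragment extension used when assigning reads to
#'   features. The default `NULL` counts the reads themselves, matching
#'   single-end pseudoalignment where the read sequence alone decides the
#'   assignment; extending reads across short intergenic gaps would bleed
#'   extension reads into downstream genes.
#' @param seed Integer seed controlling simulation.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), data_dir = NULL,
                            contrasts = NULL, peak = peak_params(),
                            read_length = 50L, min_support = 2L,
                            lfc = 0.5, alpha = 0.05, quant_l_frag = NULL,
                            seed = NULL) {
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, data_dir = data_dir, contrasts = contrasts,
                 peak = peak, read_length = read_length,
                 min_support = min_support, lfc = lfc, alpha = alpha,
                 quant_l_frag = quant_l_frag),
            class = "pipeline_config")
}

#' Run the full read-through discovery and DE pipeline
#'
#' Stages: (1) simulate or load the stranded dataset; (2) per mutant
#' genotype, subtract annotated reads, call intergenic peaks per replicate,
#' filter by TTS proximity and take the replicate consensus; (3) merge the
#' mutants' read-through annotations; (4) quantify transcripts alone and
#' transcripts plus read-through features; (5) test differential expression
#' (two-sided, thresholded) and read-through presence (one-sided at 0) per
#' contrast; (6) summarise the two mutants against each other. Deterministic
#' for a fixed seed.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Output directory for TSV/BED/GFF3 artefacts and the run
#'   manifest; `NULL` keeps results in memory only.
#' @return List of class `rt_pipeline`: `annotation`, `truth` (synthetic
#'   runs), `sample_sheet`, `rt_calls` (per genotype), `rt_merged`, `counts`,
#'   `de` and `rt_presence` (per contrast), `comparison` (when two mutants
#'   are tested), `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  data <- stage("input", {
    if (!is.null(cfg$sim)) {
      sim <- simulate_dataset(cfg$sim)
      list(annotation = sim$annotation, sample_sheet = sim$sample_sheet,
           reads = sim$reads, truth = sim$truth)
    } else if (!is.null(cfg$data_dir)) {
      read_dataset(cfg$data_dir)
    } else {
      abort("config provides neither `sim` nor `data_dir`")
    }
  })
  ann <- data$annotation
  sheet <- data$sample_sheet
  genotypes <- unique(sheet$genotype)
  contrasts <- cfg$contrasts %||%
    purrr::map(setdiff(genotypes, genotypes[1]), \(g) c(g, genotypes[1]))
  for (ct in contrasts) {
    if (!all(ct %in% genotypes)) {
      abort(sprintf("contrast (%s) references unknown genotypes",
                    paste(ct, collapse = " vs ")))
    }
  }
  mutants <- unique(purrr::map_chr(contrasts, 1))

  rt_calls <- stage("readthrough", {
    calls <- purrr::map(mutants, function(g) {
      reps <- sheet$sample_id[sheet$genotype == g]
      detect_readthrough(data$reads[reps], ann, params = cfg$peak,
                         read_length = cfg$read_length,
                         min_support = cfg$min_support)
    })
    names(calls) <- mutants
    calls
  })
  rt_merged <- stage("merge", {
    if (length(rt_calls) >= 2) {
      purrr::reduce(rt_calls, merge_genotype_annotations)
    } else if (length(rt_calls) == 1) {
      rt_calls[[1]]
    } else {
      empty_rt_calls()
    }
  })
  counts <- stage("quantify",
    build_count_tables(data$reads, sheet, ann, rt_merged,
                       l_frag = cfg$quant_l_frag))
  de <- stage("test", {
    res <- purrr::map(contrasts, \(ct)
      nb_wald_test(counts$transcripts, sheet, contrast = ct,
                   lfc_threshold = cfg$lfc, alpha = cfg$alpha))
    names(res) <- purrr::map_chr(contrasts, 1)
    res
  })
  rt_presence <- stage("test_rt", {
    rt_ids <- paste0(rt_merged$gene_id, "_RT")
    res <- purrr::map(contrasts, function(ct) {
      if (length(rt_ids) == 0) return(NULL)
      full <- nb_wald_test(counts$transcripts_rt, sheet, contrast = ct,
                           lfc_threshold = 0, alternative = "greater",
                           alpha = cfg$alpha)
      out <- filter(as_tibble(full), .data$feature_id %in% rt_ids) |>
        mutate(gene_id = sub("_RT$", "", .data$feature_id))
      # BH within the read-through analysis only
      out$padj <- bh_adjust(out$pvalue)
      out$call <- de_call(out$log2fc, out$padj, 0, cfg$alpha, "greater")
      out
    })
    names(res) <- purrr::map_chr(contrasts, 1)
    res
  })
  comparison <- if (length(de) >= 2) {
    a <- names(de)[1]; b <- names(de)[2]
    summarise_comparison(de[[a]], de[[b]],
                         rt_present_calls(rt_presence[[a]], rt_calls[[a]]),
                         rt_present_calls(rt_presence[[b]], rt_calls[[b]]),
                         ann, labels = c(a, b))
  }
  result <- structure(
    list(annotation = ann, truth = data$truth, sample_sheet = sheet,
         rt_calls = rt_calls, rt_merged = rt_merged, counts = counts,
         de = de, rt_presence = rt_presence, comparison = comparison,
         config = cfg),
    class = "rt_pipeline")
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

# genotype's consensus calls restricted to genes whose presence test passed
rt_present_calls <- function(presence, calls) {
  if (is.null(presence) || nrow(calls) == 0) return(empty_rt_calls())
  keep <- presence$gene_id[presence$call == "up"]
  filter(as_tibble(calls), .data$gene_id %in% keep)
}

#' Read-through genes declared present in a pipeline run
#'
#' A gene is declared a read-through in a genotype when it has a consensus
#' extension and its `_RT` feature passes the one-sided presence test
#' (log2FC > 0, FDR <= alpha) against the reference.
#'
#' @param result An [run_pipeline()] result.
#' @param genotype Mutant genotype name.
#' @return Character vector of gene ids.
#' @export
readthrough_genes <- function(result, genotype) {
  rt_present_calls(result$rt_presence[[genotype]],
                   result$rt_calls[[genotype]])$gene_id
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- result$annotation
  for (g in names(result$rt_calls)) {
    calls <- result$rt_calls[[g]]
    write_bed6(mutate(as_tibble(calls), score = .data$n_support),
               file.path(outdir, sprintf("readthrough_%s.bed", g)))
    write_readthrough_gff3(calls, ann,
                           file.path(outdir, sprintf("readthrough_%s.gff3", g)))
  }
  write_bed6(mutate(as_tibble(result$rt_merged), score = .data$n_support),
             file.path(outdir, "readthrough_merged.bed"))
  write_count_table(result$counts$transcripts,
                    file.path(outdir, "counts_transcripts.tsv"))
  write_count_table(result$counts$transcripts_rt,
                    file.path(outdir, "counts_transcripts_rt.tsv"))
  for (g in names(result$de)) {
    write_de_table(result$de[[g]], file.path(outdir, sprintf("de_%s.tsv", g)))
    if (!is.null(result$rt_presence[[g]])) {
      readr::write_tsv(result$rt_presence[[g]],
                       file.path(outdir, sprintf("rt_presence_%s.tsv", g)),
                       progress = FALSE)
    }
  }
  if (!is.null(result$comparison)) {
    readr::write_tsv(result$comparison$summary,
                     file.path(outdir, "comparison_summary.tsv"),
                     progress = FALSE)
    readr::write_tsv(result$comparison$biotypes,
                     file.path(outdir, "comparison_biotypes.tsv"),
                     progress = FALSE)
  }
  manifest <- list(
    package = "readthroughr",
    version = as.character(utils::packageVersion("readthroughr")),
    r_version = R.version.string,
    seed = result$config$sim$seed,
    parameters = list(
      read_length = result$config$read_length,
      tts_max_distance = 2L * result$config$read_length,
      min_support = result$config$min_support,
      lfc = result$config$lfc, alpha = result$config$alpha,
      peak = unclass(result$config$peak)),
    n_units = nrow(ann),
    n_samples = nrow(result$sample_sheet),
    n_readthrough = purrr::map_int(result$rt_calls, nrow))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.rt_pipeline <- function(x, ...) {
  cat(sprintf("# readthroughr pipeline run: %d units, %d samples\n",
              nrow(x$annotation), nrow(x$sample_sheet)))
  for (g in names(x$rt_calls)) {
    cat(sprintf("  %s: %d consensus read-throughs, %d declared present\n",
                g, nrow(x$rt_calls[[g]]),
                length(readthrough_genes(x, g))))
  }
  for (g in names(x$de)) {
    s <- de_sets(x$de[[g]])
    cat(sprintf("  DE %s vs reference: %d up, %d down\n",
                g, length(s$up), length(s$down)))
  }
  invisible(x)
}

#' Recovery metrics of a synthetic pipeline run against its ground truth
#'
#' For each mutant genotype: sensitivity and precision of the declared
#' read-through genes against the planted ones, and the observed false
#' discovery rate and sensitivity of the up/down DE calls against planted
#' fold changes (restricted to genes with baseline mean at least
#' `min_mu` for sensitivity, as low-count genes carry no power).
#'
#' @param result A [run_pipeline()] result with a `truth` table.
#' @param min_mu Baseline-mean floor for the DE sensitivity denominator.
#' @return Tibble with one row per genotype: `rt_sensitivity`,
#'   `rt_precision`, `de_fdr`, `de_sensitivity`.
#' @export
recovery_metrics <- function(result, min_mu = 100) {
  truth <- result$truth
  if (is.null(truth)) abort("pipeline run has no ground truth (not synthetic)")
  truth <- as_tibble(truth)
  purrr::map_dfr(names(result$de), function(g) {
    tt <- filter(truth, .data$genotype == g)
    called_rt <- readthrough_genes(result, g)
    true_rt <- tt$gene_id[tt$is_readthrough]
    sets <- de_sets(result$de[[g]])
    called_up <- sets$up; called_down <- sets$down
    true_up <- tt$gene_id[tt$lfc > 0]
    true_down <- tt$gene_id[tt$lfc < 0]
    called_de <- c(called_up, called_down)
    false_de <- c(setdiff(called_up, true_up), setdiff(called_down, true_down))
    power_genes <- tt$gene_id[tt$mu >= min_mu & tt$lfc != 0]
    recovered <- c(intersect(called_up, intersect(true_up, power_genes)),
                   intersect(called_down, intersect(true_down, power_genes)))
    tibble(
      genotype = g,
      rt_sensitivity = if (length(true_rt) > 0)
        length(intersect(called_rt, true_rt)) / length(true_rt) else NA_real_,
      rt_precision = if (length(called_rt) > 0)
        length(intersect(called_rt, true_rt)) / length(called_rt) else NA_real_,
      de_fdr = if (length(called_de) > 0)
        length(false_de) / length(called_de) else 0,
      de_sensitivity = if (length(power_genes) > 0)
        length(recovered) / length(power_genes) else NA_real_)
  })
}
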