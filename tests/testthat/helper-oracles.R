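# Brute-force oracles, deliberately naive and independent of the package's
# implementation paths.

# per-base boolean scan complement
oracle_complement <- function(units, chrom_len, chrom, strand) {
  covered <- logical(chrom_len)
  u <- units[units$chrom == chrom & units$strand == strand, ]
  for (i in seq_len(nrow(u))) {
    covered[(u$start[i] + 1):u$end[i]] <- TRUE
  }
  free <- which(!covered)
  if (length(free) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  brk <- c(0, which(diff(free) > 1), length(free))
  purrr::map_dfr(seq_len(length(brk) - 1), function(j) {
    seg <- free[(brk[j] + 1):brk[j + 1]]
    tibble::tibble(chrom = chrom, start = min(seg) - 1L, end = max(seg))
  })
}

# exhaustive pairwise downstream-neighbour scan
oracle_orientation <- function(ann) {
  u <- dplyr::as_tibble(ann)
  sapply(seq_len(nrow(u)), function(i) {
    g <- u[i, ]
    best <- NULL; best_key <- NULL
    for (j in seq_len(nrow(u))) {
      if (j == i) next
      o <- u[j, ]
      if (o$chrom != g$chrom) next
      if (g$strand == "+") {
        if (o$end <= g$end) next
        gap <- max(0, o$start - g$end)
      } else {
        if (o$start >= g$start) next
        gap <- max(0, g$start - o$end)
      }
      key <- list(gap, o$start, o$gene_id)
      if (is.null(best) ||
          gap < best_key[[1]] ||
          (gap == best_key[[1]] && o$start < best_key[[2]]) ||
          (gap == best_key[[1]] && o$start == best_key[[2]] &&
             o$gene_id < best_key[[3]])) {
        best <- o; best_key <- key
      }
    }
    if (is.null(best)) "isolated"
    else if (best$strand == g$strand) "tandem"
    else "convergent"
  })
}

# exhaustive nearest-TTS scan for one stranded interval
oracle_nearest_tts <- function(iv, ann) {
  u <- three_prime_end(ann)
  u <- u[u$chrom == iv$chrom & u$strand == iv$strand, ]
  bound <- if (iv$strand == "+") iv$start else iv$end
  dist <- if (iv$strand == "+") bound - u$tts else u$tts - bound
  ok <- which(dist >= 0)
  if (length(ok) == 0) return(NULL)
  best <- ok[which.min(dist[ok])]
  list(gene_id = u$gene_id[best], distance = dist[best])
}

# naive per-fragment maximal-overlap assignment
oracle_assign <- function(frags, features) {
  sapply(seq_len(nrow(frags)), function(i) {
    f <- frags[i, ]
    ov <- integer(nrow(features)); d5 <- integer(nrow(features))
    for (j in seq_len(nrow(features))) {
      ft <- features[j, ]
      if (ft$chrom != f$chrom || ft$strand != f$strand) { ov[j] <- 0L; next }
      ov[j] <- max(0L, min(f$end, ft$end) - max(f$start, ft$start))
      f5 <- if (f$strand == "+") f$start else f$end
      ft5 <- if (ft$strand == "+") ft$start else ft$end
      d5[j] <- abs(f5 - ft5)
    }
    if (max(ov) == 0) return("__unassigned__")
    cand <- which(ov == max(ov))
    cand <- cand[d5[cand] == min(d5[cand])]
    if (length(cand) > 1) "__unassigned__" else features$feature_id[cand]
  })
}

# literal step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  sapply(seq_len(m), function(i) {
    min(1, min(sapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) m * p[j] / rank(p, ties.method = "max")[j] else Inf
    })))
  })
}

# hypergeometric upper tail by direct combinatorial summation
oracle_hyper <- function(k, n1, n2, N) {
  j <- k:min(n1, n2)
  sum(choose(n1, j) * choose(N - n1, n2 - j)) / choose(N, n2)
}

# per-base coverage recount
oracle_coverage <- function(frags, chrom_len, chrom, strand) {
  v <- integer(chrom_len)
  f <- frags[frags$chrom == chrom & frags$strand == strand, ]
  for (i in seq_len(nrow(f))) {
    idx <- (f$start[i] + 1):f$end[i]
    v[idx] <- v[idx] + 1L
  }
  v
}

# expand a coverage tibble back to a per-base vector
coverage_vector <- function(cov, chrom_len, chrom, strand) {
  v <- integer(chrom_len)
  cv <- cov[cov$chrom == chrom & cov$strand == strand, ]
  for (i in seq_len(nrow(cv))) {
    v[(cv$start[i] + 1):cv$end[i]] <- cv$depth[i]
  }
  v
}
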