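# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force shared-core: scan every contiguous marker interval covering
# both variant flanks and return the widest span (Mb) on which *all*
# haplotypes carry the founder allele (missing = 0 is compatible under the
# permissive policy). Returns 0 when no such interval exists.
brute_force_core_span <- function(allele_matrix, founder, pos_bp, variant_bp,
                                  permissive = TRUE) {
  n_markers <- length(pos_bp)
  if (variant_bp <= pos_bp[1]) {
    lo <- 1L; hi <- 1L
  } else if (variant_bp >= pos_bp[n_markers]) {
    lo <- n_markers; hi <- n_markers
  } else if (any(pos_bp == variant_bp)) {
    lo <- hi <- which(pos_bp == variant_bp)[1]
  } else {
    lo <- max(which(pos_bp < variant_bp)); hi <- lo + 1L
  }
  ok <- function(i, j) {
    sub <- allele_matrix[, i:j, drop = FALSE]
    f <- founder[i:j]
    all(apply(sub, 1, function(a) {
      all(ifelse(a == 0L, permissive, a == rep_len(f, length(a))))
    }))
  }
  best <- NA_real_
  for (i in seq_len(lo)) {
    for (j in hi:n_markers) {
      if (ok(i, j)) {
        span <- (pos_bp[j] - pos_bp[i]) / 1e6
        if (is.na(best) || span > best) best <- span
      }
    }
  }
  if (is.na(best)) 0 else best
}

# Independent modal-allele rule (most frequent non-missing, ties to the
# smallest id), re-implemented from scratch for the oracle.
brute_force_founder <- function(allele_matrix) {
  apply(allele_matrix, 2, function(a) {
    a <- a[a != 0L]
    counts <- sort(table(a), decreasing = TRUE)
    cand <- as.integer(names(counts)[counts == counts[1]])
    min(cand)
  })
}

# Closed-form 2x2 chi-square statistic without continuity correction.
chisq_2x2_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Random small haplotype-panel instance for property tests.
random_core_instance <- function() {
  n_markers <- sample(3:8, 1)
  n_haps <- sample(2:6, 1)
  pos <- sort(sample(1:50, n_markers)) * 1e6
  variant_bp <- runif(1, pos[1] + 1, pos[n_markers] - 1)
  founder <- sample(1:3, n_markers, replace = TRUE)
  m <- matrix(0L, n_haps, n_markers)
  for (i in seq_len(n_haps)) {
    for (j in seq_len(n_markers)) {
      u <- runif(1)
      m[i, j] <- if (u < 0.6) founder[j] else if (u < 0.7) 0L
                 else sample(setdiff(1:3, founder[j]), 1)
    }
  }
  # every marker needs at least one typed allele
  for (j in seq_len(n_markers)) {
    if (all(m[, j] == 0L)) m[1, j] <- founder[j]
  }
  map <- marker_map(paste0("M", seq_len(n_markers)), "chr1", pos)
  haps <- dplyr::bind_cols(
    tibble::tibble(haplotype_id = paste0("H", seq_len(n_haps)), carrier = 1L),
    tibble::as_tibble(matrix(m, n_haps, n_markers,
                             dimnames = list(NULL, paste0("allele_M", seq_len(n_markers)))))
  )
  list(map = map, haps = haps, variant_bp = variant_bp,
       allele_matrix = m, founder = founder, pos = pos)
}

# Temp file helper that testthat cleans up at the end of the test run.
withr_tempfile <- function(ext = ".tsv") {
  tempfile(fileext = ext)
}
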