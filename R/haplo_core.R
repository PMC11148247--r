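#' Infer the founder allele at each marker
#'
#' The founder allele is taken to be the most frequent non-missing allele
#' among the variant-carrying haplotypes at each marker; ties are broken
#' deterministically towards the smallest allele id.
#'
#' @param haps Wide haplotype tibble restricted to (or containing) carrier
#'   haplotypes; only rows with `carrier == 1` are used when a `carrier`
#'   column is present.
#' @param map Marker map (see [marker_map()]).
#'
#' @return A tibble with columns `marker_id` and `allele`.
#' @export
infer_founder_alleles <- function(haps, map) {
  map <- validate_marker_map(map)
  if ("carrier" %in% names(haps) && any(haps$carrier == 1)) {
    haps <- dplyr::filter(haps, .data$carrier == 1)
  }
  if (nrow(haps) == 0) {
    fh_abort("need at least one carrier haplotype", "founderhap_domain_error")
  }
  m <- hap_allele_matrix(haps, map)
  allele <- vapply(seq_len(ncol(m)), function(j) {
    a <- m[, j]
    a <- a[a != 0L]
    if (length(a) == 0) {
      fh_abort(
        sprintf("marker %s has no non-missing alleles", map$marker_id[j]),
        "founderhap_all_missing_marker"
      )
    }
    counts <- table(a)
    top <- as.integer(names(counts)[counts == max(counts)])
    min(top)
  }, integer(1))
  tibble(marker_id = map$marker_id, allele = allele)
}

# Does allele a match founder f under the missing policy?
allele_matches <- function(a, f, missing_policy) {
  if (a == 0L) return(missing_policy == "permissive")
  a == f
}

#' Maximal founder-concordant marker interval of one haplotype
#'
#' Finds the maximal contiguous run of markers containing the variant locus
#' on which a haplotype carries the founder allele. The run must include
#' both markers immediately flanking the variant; a haplotype discordant at
#' either flank is not founder-like around the variant and yields an empty
#' interval. Under the `"permissive"` missing policy (the default, suited to
#' microsatellite dropout) a missing allele does not break the run; under
#' `"strict"` it does.
#'
#' @param hap A single-row haplotype tibble, or a named/plain integer vector
#'   of alleles in map order (0 = missing).
#' @param founder Founder alleles as returned by [infer_founder_alleles()]
#'   (or an integer vector in map order).
#' @param map Marker map.
#' @param variant_bp Physical position of the variant (bp).
#' @param missing_policy `"permissive"` or `"strict"`.
#'
#' @return A tibble with one row: `first`, `last` (marker indices; `NA` for
#'   an empty interval), `n_markers`, `span_mb`.
#' @export
concordant_interval <- function(hap, founder, map, variant_bp,
                                missing_policy = c("permissive", "strict")) {
  missing_policy <- match.arg(missing_policy)
  map <- validate_marker_map(map)
  alleles <- hap_as_vector(hap, map)
  f <- founder_as_vector(founder, map)
  fl <- flank_indices(map, variant_bp)
  ok <- vapply(seq_len(nrow(map)), function(j) {
    allele_matches(alleles[j], f[j], missing_policy)
  }, logical(1))
  if (!ok[fl[1]] || !ok[fl[2]]) {
    return(tibble(first = NA_integer_, last = NA_integer_,
                  n_markers = 0L, span_mb = 0))
  }
  first <- fl[1]
  while (first > 1L && ok[first - 1L]) first <- first - 1L
  last <- fl[2]
  while (last < nrow(map) && ok[last + 1L]) last <- last + 1L
  tibble(
    first = first, last = last,
    n_markers = last - first + 1L,
    span_mb = (map$pos_bp[last] - map$pos_bp[first]) / 1e6
  )
}

hap_as_vector <- function(hap, map) {
  if (is.data.frame(hap)) {
    stopifnot(nrow(hap) == 1)
    as.integer(hap_allele_matrix(hap, map)[1, ])
  } else {
    as.integer(rep_len(hap, nrow(map)))
  }
}

founder_as_vector <- function(founder, map) {
  if (is.data.frame(founder)) {
    stopifnot(all(map$marker_id %in% founder$marker_id))
    as.integer(founder$allele[match(map$marker_id, founder$marker_id)])
  } else {
    as.integer(rep_len(founder, nrow(map)))
  }
}

#' Shared founder core haplotype across carriers
#'
#' Intersects the founder-concordant intervals of all carrier haplotypes to
#' delineate the core haplotype shared by the whole set, then produces a
#' recombinant-exclusion ladder: haplotypes are removed one at a time,
#' greedily choosing at each step the haplotype whose removal maximally
#' widens the shared interval (ties towards the earlier row), recording the
#' `(n remaining, shared span)` pairs. The span convention is the physical
#' distance between the outermost concordant markers (a conservative lower
#' bound on the true shared segment, whose breakpoints lie somewhere beyond
#' them).
#'
#' @param haps Wide haplotype tibble of carrier haplotypes (rows with
#'   `carrier == 1` are used when the column is present; >= 2 required).
#' @param map Marker map.
#' @param variant_bp Physical position of the variant (bp).
#' @param missing_policy `"permissive"` (default) or `"strict"`; see
#'   [concordant_interval()].
#'
#' @return An object of class `core_result`: a list with `founder` (per
#'   marker allele tibble), `intervals` (per haplotype), `core` (one-row
#'   tibble: `first`, `last`, `n_haplotypes`, `span_mb`), and `ladder`
#'   (tibble of `n`, `first`, `last`, `span_mb`, `dropped`). Supports
#'   [generics::tidy()] (the ladder) and [generics::glance()].
#' @export
shared_core <- function(haps, map, variant_bp,
                        missing_policy = c("permissive", "strict")) {
  missing_policy <- match.arg(missing_policy)
  map <- validate_marker_map(map)
  if ("carrier" %in% names(haps)) {
    haps <- dplyr::filter(haps, .data$carrier == 1)
  }
  if (nrow(haps) < 2) {
    fh_abort("shared_core needs at least two carrier haplotypes",
             "founderhap_domain_error")
  }
  if (!"haplotype_id" %in% names(haps)) {
    haps$haplotype_id <- paste0("H", seq_len(nrow(haps)))
  }
  founder <- infer_founder_alleles(haps, map)
  intervals <- purrr::map(seq_len(nrow(haps)), function(i) {
    concordant_interval(haps[i, ], founder, map, variant_bp, missing_policy)
  }) |> list_rbind()
  intervals <- bind_cols(tibble(haplotype_id = haps$haplotype_id), intervals)

  core_of <- function(idx) {
    sub <- intervals[idx, ]
    if (any(is.na(sub$first))) {
      return(list(first = NA_integer_, last = NA_integer_, span = 0))
    }
    first <- max(sub$first); last <- min(sub$last)
    if (first > last) {
      return(list(first = NA_integer_, last = NA_integer_, span = 0))
    }
    list(first = first, last = last,
         span = (map$pos_bp[last] - map$pos_bp[first]) / 1e6)
  }

  all_idx <- seq_len(nrow(intervals))
  full <- core_of(all_idx)
  if (is.na(full$first)) {
    warning("no marker interval is shared by all carrier haplotypes; core span is 0")
  }
  ladder <- list(tibble(
    n = length(all_idx), first = full$first, last = full$last,
    span_mb = full$span, dropped = NA_character_
  ))
  idx <- all_idx
  while (length(idx) > 2L) {
    spans <- vapply(seq_along(idx), function(k) core_of(idx[-k])$span, numeric(1))
    k <- which.max(spans) # ties -> earliest row
    dropped <- intervals$haplotype_id[idx[k]]
    idx <- idx[-k]
    step <- core_of(idx)
    ladder[[length(ladder) + 1L]] <- tibble(
      n = length(idx), first = step$first, last = step$last,
      span_mb = step$span, dropped = dropped
    )
  }
  ladder <- list_rbind(ladder)

  structure(
    list(
      founder = founder,
      intervals = intervals,
      core = tibble(
        first = full$first, last = full$last,
        n_haplotypes = nrow(intervals), span_mb = full$span
      ),
      ladder = ladder,
      map = map,
      variant_bp = variant_bp
    ),
    class = "core_result"
  )
}

#' @export
print.core_result <- function(x, ...) {
  cat(sprintf(
    "Shared founder core: %.3g Mb across %d haplotypes (markers %s..%s)\n",
    x$core$span_mb, x$core$n_haplotypes,
    ifelse(is.na(x$core$first), "-", x$map$marker_id[x$core$first]),
    ifelse(is.na(x$core$last), "-", x$map$marker_id[x$core$last])
  ))
  cat("Recombinant-exclusion ladder:\n")
  print(x$ladder)
  invisible(x)
}

#' Synthetic replica of the proband haplotype panel
#'
#' A constructed 24-haplotype panel over a 13-marker, 26.4 Mb microsatellite
#' map around a chromosome 11 variant locus, built so that the shared core
#' across all 24 haplotypes spans 1.19 Mb while 19 of the 24 share a wider
#' 13.8 Mb haplotype, with 5 nested recombinants truncating the common
#' segment. The marker coordinates and allele assignments are synthetic:
#' they reproduce the sharing *structure* of a real founder panel (its
#' exclusion ladder), not any real individual's genotypes.
#'
#' @return A list with `map` (marker map), `haps` (24 phased carrier
#'   haplotypes, wide format) and `variant_bp`.
#' @export
#' @examples
#' rep <- synthetic_proband_haplotypes()
#' res <- shared_core(rep$haps, rep$map, rep$variant_bp)
#' res$core$span_mb # 1.19
synthetic_proband_haplotypes <- function() {
  map <- marker_map(
    marker_id = paste0("MS", sprintf("%02d", 1:13)),
    chrom = "chr11",
    pos_bp = c(34.0e6, 37.0e6, 40.0e6, 43.0e6, 45.0e6, 46.8e6, 47.99e6,
               49.0e6, 51.0e6, 53.8e6, 55.0e6, 58.0e6, 60.4e6)
  )
  variant_bp <- 47357175
  n_markers <- nrow(map)
  founder <- rep(3L, n_markers)
  # A haplotype concordant exactly on markers first..last, discordant
  # (allele 5) immediately outside.
  make_hap <- function(first, last) {
    a <- founder
    if (first > 1) a[seq_len(first - 1)] <- 5L
    if (last < n_markers) a[seq(last + 1, n_markers)] <- 5L
    a
  }
  rows <- vector("list", 24)
  # 19 haplotypes jointly sharing markers MS03..MS10 (13.8 Mb): two carry
  # the delimiting breaks, the rest are unrecombined over the whole map.
  rows[[1]] <- make_hap(3, 13)
  rows[[2]] <- make_hap(1, 10)
  for (i in 3:19) rows[[i]] <- make_hap(1, 13)
  # 5 recombinants with nested concordant intervals truncating the shared
  # segment down to MS06..MS07 (1.19 Mb).
  rows[[20]] <- make_hap(6, 7)
  rows[[21]] <- make_hap(5, 7)
  rows[[22]] <- make_hap(5, 8)
  rows[[23]] <- make_hap(4, 9)
  rows[[24]] <- make_hap(4, 10)
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("allele_", map$marker_id)
  haps <- bind_cols(
    tibble(haplotype_id = sprintf("P%02d", 1:24), carrier = 1L),
    as_tibble(m)
  )
  list(map = map, haps = haps, variant_bp = variant_bp)
}
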