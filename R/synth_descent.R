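#' Simulate founder-haplotype descent with recombination
#'
#' Generates phased carrier and non-carrier haplotypes descending from a
#' single founder chromosome `g` generations back. Each marker is treated
#' marginally with respect to the variant locus, matching the single-marker
#' LD dating model: a carrier haplotype retains the founder allele at marker
#' *i* with probability `(1 - r_i)^g`, where `r_i` is the Haldane
#' recombination fraction for the marker's map distance to the variant;
#' otherwise (an ancestral recombination separated marker from variant) the
#' allele is redrawn from the background population, where the founder
#' allele segregates at frequency `pop_freq_i`. Non-carrier haplotypes draw
#' every allele from the background. There is no marker mutation and no
#' crossover interference along the chromosome.
#'
#' @param map Marker map (see [marker_map()]).
#' @param variant_bp Physical position of the variant (bp).
#' @param founder_alleles Integer vector, the founder allele at each marker
#'   (map order).
#' @param pop_freqs Numeric vector in `[0, 1)`: background frequency of the
#'   founder allele at each marker (the ground-truth `Pn2`).
#' @param g Number of generations since the founder event (>= 1).
#' @param n_carriers,n_noncarriers Numbers of haplotypes to draw.
#' @param n_alleles Number of distinct alleles segregating at each marker
#'   (default 6); non-founder background draws are uniform over the other
#'   allele ids.
#' @param seed Integer seed; the run is fully reproducible given it.
#'
#' @return A wide haplotype tibble: `haplotype_id`, `carrier` (1/0), one
#'   `allele_<marker_id>` column per marker.
#' @export
#' @examples
#' map <- marker_map("M1", "chr11", 2e6)
#' simulate_descent(map, variant_bp = 1e6, founder_alleles = 1,
#'                  pop_freqs = 0.2, g = 3, n_carriers = 5,
#'                  n_noncarriers = 5, seed = 1)
simulate_descent <- function(map, variant_bp, founder_alleles, pop_freqs,
                             g, n_carriers, n_noncarriers = 0,
                             n_alleles = 6L, seed = 1L) {
  map <- validate_marker_map(map)
  n_markers <- nrow(map)
  stopifnot(g >= 1, n_carriers >= 1, n_noncarriers >= 0, n_alleles >= 2)
  founder_alleles <- as.integer(rep_len(founder_alleles, n_markers))
  pop_freqs <- rep_len(pop_freqs, n_markers)
  if (any(pop_freqs < 0 | pop_freqs > 1)) {
    fh_abort("population founder-allele frequencies must lie in [0, 1]",
             "founderhap_domain_error")
  }
  d <- marker_d_morgans(map, variant_bp)
  r <- haldane_r(d)
  uninformative <- which(r == 0 & pop_freqs == 1)
  if (length(uninformative) > 0) {
    warning(sprintf(
      "marker(s) %s are uninformative (zero distance, fixed background allele)",
      toString(map$marker_id[uninformative])
    ))
  }
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  withr_seed({
    draw_background <- function(n, j) {
      # founder allele with prob pop_freqs[j], else uniform over the others
      other <- setdiff(seq_len(n_alleles), founder_alleles[j])
      is_founder <- runif(n) < pop_freqs[j]
      out <- integer(n)
      out[is_founder] <- founder_alleles[j]
      n_other <- sum(!is_founder)
      if (n_other > 0) {
        out[!is_founder] <- sample(other, n_other, replace = TRUE)
      }
      out
    }
    carrier_m <- matrix(0L, n_carriers, n_markers)
    retain_p <- (1 - r)^g
    for (j in seq_len(n_markers)) {
      retained <- runif(n_carriers) < retain_p[j]
      carrier_m[, j] <- ifelse(retained, founder_alleles[j], 0L)
      n_rec <- sum(!retained)
      if (n_rec > 0) carrier_m[!retained, j] <- draw_background(n_rec, j)
    }
    noncar_m <- matrix(0L, n_noncarriers, n_markers)
    if (n_noncarriers > 0) {
      for (j in seq_len(n_markers)) {
        noncar_m[, j] <- draw_background(n_noncarriers, j)
      }
    }
    m <- rbind(carrier_m, noncar_m)
    colnames(m) <- paste0("allele_", map$marker_id)
    bind_cols(
      tibble(
        haplotype_id = c(
          sprintf("C%05d", seq_len(n_carriers)),
          if (n_noncarriers > 0) sprintf("N%05d", seq_len(n_noncarriers))
        ),
        carrier = rep(c(1L, 0L), c(n_carriers, n_noncarriers))
      ),
      as_tibble(m)
    )
  })
}

#' Simulate a targeted-panel read-depth matrix
#'
#' Builds a samples-by-ROI count matrix with optional heterozygous CNVs
#' embedded as dosage drops: an unaffected ROI has expected depth
#' `mean_depth`, a deleted ROI `dosage_factor * mean_depth` (0.5 for a
#' heterozygous deletion). In `"none"` noise mode the counts equal those
#' expectations exactly (rounded to integers); in `"poisson"` mode they are
#' Poisson draws with those means.
#'
#' @param n_samples Number of samples (ignored when `deleted_rois` names
#'   more samples).
#' @param roi_ids Ordered character vector of ROI names.
#' @param control_rois Non-empty subset of `roi_ids`; must not intersect any
#'   deleted set.
#' @param mean_depth Expected read depth of an unaffected ROI (> 0).
#' @param deleted_rois Named list mapping sample id to the character vector
#'   of its deleted ROIs (default: none).
#' @param dosage_factor Dosage of the deleted ROIs relative to diploid, in
#'   `(0, 1]`; default 0.5 (heterozygous deletion).
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed.
#'
#' @return A count tibble: `sample_id` plus one integer column per ROI.
#' @export
simulate_depth <- function(n_samples, roi_ids, control_rois, mean_depth,
                           deleted_rois = list(), dosage_factor = 0.5,
                           noise = c("none", "poisson"), seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_samples >= 1, mean_depth > 0,
            dosage_factor > 0, dosage_factor <= 1)
  if (length(control_rois) == 0) {
    fh_abort("control ROI set must be non-empty", "founderhap_domain_error")
  }
  stopifnot(all(control_rois %in% roi_ids))
  overlap <- intersect(control_rois, unlist(deleted_rois, use.names = FALSE))
  if (length(overlap) > 0) {
    fh_abort(paste0("control ROI(s) appear in a deleted set: ", toString(overlap)),
             "founderhap_domain_error")
  }
  sample_ids <- paste0("S", seq_len(n_samples))
  if (length(deleted_rois) > 0) {
    stopifnot(!is.null(names(deleted_rois)))
    sample_ids <- union(sample_ids, names(deleted_rois))
  }
  mu <- matrix(mean_depth, length(sample_ids), length(roi_ids),
               dimnames = list(sample_ids, roi_ids))
  for (s in names(deleted_rois)) {
    stopifnot(all(deleted_rois[[s]] %in% roi_ids))
    mu[s, deleted_rois[[s]]] <- dosage_factor * mean_depth
  }
  m <- if (noise == "none") {
    round(mu)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    matrix(rpois(length(mu), mu), nrow(mu), ncol(mu), dimnames = dimnames(mu))
  }
  storage.mode(m) <- "integer"
  out <- bind_cols(tibble(sample_id = sample_ids), as_tibble(m))
  attr(out, "control_rois") <- control_rois
  out
}
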