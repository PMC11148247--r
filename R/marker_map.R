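#' Construct and validate a marker map
#'
#' A marker map is an ordered table of polymorphic loci (microsatellites or
#' SNPs) flanking a variant of interest, with physical (bp) and genetic (cM)
#' positions. Genetic positions default to `pos_bp / 1e6`, i.e. the common
#' 1 Mb ~ 1 cM approximation for the human genome; supply a `pos_cm` column
#' to override it with measured map distances.
#'
#' @param marker_id Character vector of marker names (e.g. `"D11S1785"`).
#' @param chrom Chromosome label, recycled to the number of markers.
#' @param pos_bp Physical positions in base pairs; must be strictly
#'   increasing.
#' @param pos_cm Optional genetic positions in centimorgans. Defaults to
#'   `pos_bp / 1e6`.
#'
#' @return A tibble with columns `marker_id`, `chrom`, `pos_bp`, `pos_cm`,
#'   one row per marker, ordered by physical position.
#' @export
#' @examples
#' marker_map(c("M1", "M2", "M3"), "chr11", c(1e6, 3e6, 5e6))
marker_map <- function(marker_id, chrom, pos_bp, pos_cm = NULL) {
  if (is.null(pos_cm)) pos_cm <- pos_bp / 1e6
  map <- tibble(
    marker_id = as.character(marker_id),
    chrom = rep_len(as.character(chrom), length(marker_id)),
    pos_bp = as.numeric(pos_bp),
    pos_cm = as.numeric(pos_cm)
  )
  validate_marker_map(map)
}

#' @rdname marker_map
#' @param map A marker-map tibble to validate.
#' @export
validate_marker_map <- function(map) {
  required <- c("marker_id", "pos_bp")
  missing <- setdiff(required, names(map))
  if (length(missing) > 0) {
    fh_abort(
      paste0("marker map is missing column(s): ", toString(missing)),
      "founderhap_schema_error"
    )
  }
  if (anyDuplicated(map$marker_id)) {
    fh_abort("duplicate marker ids in marker map", "founderhap_schema_error")
  }
  bad <- which(diff(map$pos_bp) <= 0)
  if (length(bad) > 0) {
    fh_abort(
      sprintf(
        "marker positions must be strictly increasing; violation at row %d (marker %s)",
        bad[1] + 1L, map$marker_id[bad[1] + 1L]
      ),
      "founderhap_schema_error"
    )
  }
  if (!"chrom" %in% names(map)) map$chrom <- NA_character_
  if (!"pos_cm" %in% names(map)) map$pos_cm <- map$pos_bp / 1e6
  as_tibble(map[, c("marker_id", "chrom", "pos_bp", "pos_cm")])
}

# Genetic position (cM) of an arbitrary bp coordinate, by linear
# interpolation of the map (extrapolating linearly at the flanks under the
# same slope as 1 Mb/cM when the map is default-scaled).
variant_cm <- function(map, variant_bp) {
  if (nrow(map) == 1L) {
    return(map$pos_cm[1] + (variant_bp - map$pos_bp[1]) / 1e6)
  }
  stats::approx(map$pos_bp, map$pos_cm, xout = variant_bp, rule = 2)$y +
    ifelse(
      variant_bp < map$pos_bp[1],
      (variant_bp - map$pos_bp[1]) / 1e6,
      ifelse(
        variant_bp > map$pos_bp[nrow(map)],
        (variant_bp - map$pos_bp[nrow(map)]) / 1e6,
        0
      )
    )
}

# Morgan distances between each marker and the variant locus.
marker_d_morgans <- function(map, variant_bp) {
  v_cm <- variant_cm(map, variant_bp)
  abs(map$pos_cm - v_cm) / 100
}

# Indices of the markers immediately flanking (or coinciding with) the
# variant position. Returns c(lo, hi); lo == hi when the variant sits on a
# marker or outside the map span (declared flank).
flank_indices <- function(map, variant_bp) {
  pos <- map$pos_bp
  if (variant_bp <= pos[1]) return(c(1L, 1L))
  n <- length(pos)
  if (variant_bp >= pos[n]) return(c(n, n))
  hit <- which(pos == variant_bp)
  if (length(hit) > 0) return(c(hit[1], hit[1]))
  lo <- max(which(pos < variant_bp))
  c(lo, lo + 1L)
}

# Extract the allele matrix (haplotypes x markers) from a wide haplotype
# tibble with allele_<marker_id> columns; 0 codes missing.
hap_allele_matrix <- function(haps, map) {
  cols <- paste0("allele_", map$marker_id)
  missing <- setdiff(cols, names(haps))
  if (length(missing) > 0) {
    fh_abort(
      paste0("haplotype table is missing allele column(s): ", toString(missing)),
      "founderhap_schema_error"
    )
  }
  m <- as.matrix(haps[, cols])
  storage.mode(m) <- "integer"
  rownames(m) <- if ("haplotype_id" %in% names(haps)) haps$haplotype_id else NULL
  colnames(m) <- map$marker_id
  m
}
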