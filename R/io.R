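#' Read and write the package's tabular file formats
#'
#' Plain-text readers and writers for the four data types the pipeline
#' exchanges. All genomic coordinates are 1-based fully-closed in these
#' files. Missing alleles are coded 0 in haplotype files (linkage-format
#' convention); missing values are empty fields in the cohort CSV.
#'
#' * marker map — TSV with columns `marker_id`, `chrom`, `pos_bp`, optional
#'   `pos_cm`; positions must be strictly increasing.
#' * haplotypes — TSV with `haplotype_id`, `carrier` (1/0) and one
#'   `allele_<marker>` column per marker.
#' * counts — TSV with `sample_id` and one integer column per ROI.
#' * cohort — CSV with the column dictionary of [build_cohort_fixture()].
#'
#' Writing then reading any of these yields an identical table.
#'
#' @param path File path.
#' @name founderhap_io
NULL

#' @rdname founderhap_io
#' @export
read_marker_map <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  validate_marker_map(tbl)
}

#' @rdname founderhap_io
#' @param map Marker-map tibble.
#' @export
write_marker_map <- function(map, path) {
  readr::write_tsv(validate_marker_map(map), path)
  invisible(path)
}

#' @rdname founderhap_io
#' @export
read_haplotypes <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("haplotype_id", "carrier")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    fh_abort(paste0("haplotype file missing column(s): ", toString(missing)),
             "founderhap_schema_error")
  }
  allele_cols <- grep("^allele_", names(tbl), value = TRUE)
  if (length(allele_cols) == 0) {
    fh_abort("haplotype file has no allele_<marker> columns",
             "founderhap_schema_error")
  }
  bad <- which(!tbl$carrier %in% c(0L, 1L))
  if (length(bad) > 0) {
    fh_abort(sprintf("invalid carrier flag on line %d", bad[1] + 1L),
             "founderhap_schema_error")
  }
  for (col in allele_cols) {
    bad <- which(is.na(tbl[[col]]) | tbl[[col]] < 0 |
                   tbl[[col]] != floor(tbl[[col]]))
    if (length(bad) > 0) {
      fh_abort(
        sprintf("unknown allele code in column %s on line %d", col, bad[1] + 1L),
        "founderhap_schema_error"
      )
    }
    tbl[[col]] <- as.integer(tbl[[col]])
  }
  tbl$carrier <- as.integer(tbl$carrier)
  tbl
}

#' @rdname founderhap_io
#' @param haps Haplotype tibble.
#' @export
write_haplotypes <- function(haps, path) {
  readr::write_tsv(haps, path)
  invisible(path)
}

#' @rdname founderhap_io
#' @export
read_counts <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(tbl)) {
    fh_abort("counts file missing sample_id column", "founderhap_schema_error")
  }
  roi_cols <- setdiff(names(tbl), "sample_id")
  for (col in roi_cols) {
    bad <- which(is.na(tbl[[col]]) | tbl[[col]] < 0)
    if (length(bad) > 0) {
      fh_abort(
        sprintf("invalid count in column %s on line %d", col, bad[1] + 1L),
        "founderhap_schema_error"
      )
    }
    tbl[[col]] <- as.integer(tbl[[col]])
  }
  tbl$sample_id <- as.character(tbl$sample_id)
  tbl
}

#' @rdname founderhap_io
#' @param counts Count tibble.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname founderhap_io
#' @export
read_control_rois <- function(path) {
  readLines(path) |> trimws() |> (\(x) x[nzchar(x)])()
}

#' @rdname founderhap_io
#' @param control_rois Character vector of control ROI ids.
#' @export
write_control_rois <- function(control_rois, path) {
  writeLines(control_rois, path)
  invisible(path)
}

#' @rdname founderhap_io
#' @export
read_cohort <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("id", "role", "genotype", "sex", "age_current",
                "hcm_phenotype")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    fh_abort(paste0("cohort file missing column(s): ", toString(missing)),
             "founderhap_schema_error")
  }
  if (!all(tbl$genotype %in% c("G+", "G-"))) {
    fh_abort("genotype must be 'G+' or 'G-'", "founderhap_schema_error")
  }
  for (col in grep("^(outcome_|hcm_|sympt|aht|smoker|has_|additional)",
                   names(tbl), value = TRUE)) {
    tbl[[col]] <- as.logical(tbl[[col]])
  }
  tbl
}

#' @rdname founderhap_io
#' @param cohort Cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}
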