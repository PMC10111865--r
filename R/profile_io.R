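#' Read a binned count profile
#'
#' Profiles are BED-like TSV files with header
#' `chrom, start, end, count, gc` (optionally `corrected`, `cn`).
#' Bins must match the layout's bin grid exactly: same chromosomes, same
#' half-open intervals, in grid order.
#'
#' @param path TSV file path.
#' @param layout A `genome_layout` the bins are validated against.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return Tibble with columns `sample_id, chrom, start, end, count, gc`
#'   (plus `corrected`/`cn` when present in the file).
#' @export
read_binned_profile <- function(path, layout, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "start", "end", "count", "gc")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("profile ", path, " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tab$sample_id <- sample_id
  validate_profile(tab, layout, where = path)
}

#' Validate a profile against a layout's bin grid
#'
#' Checks the (chrom, start, end) triples coincide with
#' [build_bin_grid()] output and that counts and GC fractions are in
#' range. The first offending bin is reported on failure.
#'
#' @param profile Profile tibble (single sample or a `sample_id` column).
#' @param layout A `genome_layout`.
#' @param where Label used in error messages.
#' @return The profile, columns reordered to grid order per sample.
#' @export
validate_profile <- function(profile, layout, where = "profile") {
  grid <- build_bin_grid(layout)
  if (!"sample_id" %in% names(profile)) profile$sample_id <- "sample"
  out <- profile |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(p, key) {
      if (nrow(p) != nrow(grid)) {
        stop(where, " [", key$sample_id[1], "]: expected ", nrow(grid),
             " bins on the layout grid, got ", nrow(p), call. = FALSE)
      }
      p <- dplyr::arrange(p, match(.data$chrom, layout$chrom), .data$start)
      off <- which(p$chrom != grid$chrom | p$start != grid$start |
                     p$end != grid$end)
      if (length(off) > 0) {
        i <- off[1]
        stop(where, " [", key$sample_id[1], "]: bin off the layout grid: ",
             p$chrom[i], ":", p$start[i], "-", p$end[i],
             " (expected ", grid$chrom[i], ":", grid$start[i], "-",
             grid$end[i], ")", call. = FALSE)
      }
      if (any(p$count < 0)) {
        stop(where, ": negative counts.", call. = FALSE)
      }
      if (any(p$gc < 0 | p$gc > 1)) {
        stop(where, ": gc outside [0, 1].", call. = FALSE)
      }
      if ("cn" %in% names(p) && any(!is.finite(p$cn) | p$cn < 0)) {
        stop(where, ": cn must be finite and >= 0.", call. = FALSE)
      }
      p
    }) |>
    dplyr::ungroup()
  dplyr::relocate(out, "sample_id")
}

#' Write a binned profile to TSV
#'
#' @param profile Profile tibble (one sample).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binned_profile <- function(profile, path) {
  cols <- intersect(c("chrom", "start", "end", "count", "gc",
                      "corrected", "cn"), names(profile))
  readr::write_tsv(profile[, cols], path, progress = FALSE)
  invisible(path)
}

#' Write a segment table to TSV
#'
#' BED-like, one row per segment: `chrom, start_bp, end_bp, arm, n_bins,
#' mean_cn_sample, mean_cn_ref, state`, where `state` is one of
#' E (equal), G (gain), L (loss), i (ignore).
#'
#' @param segments Segment tibble (e.g. `tidy()` of a [call_cna()] result).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  need <- c("chrom", "start_bp", "end_bp", "arm", "n_bins",
            "mean_cn_sample", "mean_cn_ref", "state")
  miss <- setdiff(need, names(segments))
  if (length(miss) > 0) {
    stop("segment table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- !segments$state %in% c("E", "G", "L", "i")
  if (any(bad)) {
    stop("invalid segment state(s): ",
         paste(unique(segments$state[bad]), collapse = ", "),
         call. = FALSE)
  }
  cols <- intersect(c("sample_id", need), names(segments))
  readr::write_tsv(segments[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read a segment table written by [write_segments()]
#' @param path TSV path.
#' @return Segment tibble.
#' @export
read_segments <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read cohort metadata
#'
#' CSV with columns `population_id, cell_line, day, growth_plus_rev,
#' growth_minus_rev` (growth values are colony-formation readouts
#' normalized to the untreated parental line) plus optional extra
#' columns. Adds `relative_growth = growth_plus_rev / growth_minus_rev`.
#'
#' @param path CSV path.
#' @return Metadata tibble.
#' @export
read_cohort_metadata <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("population_id", "cell_line", "day",
            "growth_plus_rev", "growth_minus_rev")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("cohort metadata missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(tab$growth_plus_rev < 0 | tab$growth_minus_rev < 0)) {
    stop("growth values must be >= 0.", call. = FALSE)
  }
  tab$relative_growth <- tab$growth_plus_rev / tab$growth_minus_rev
  tab
}

#' Read a cancer arm-frequency table
#'
#' CSV with columns `arm, gain_freq, loss_freq` and optional
#' `cancer_type`; frequencies are fractions in \[0, 1\]. Arm labels must
#' use the same `chrom` + `p`/`q` convention as the genome layout in use
#' (e.g. `chr8q`).
#'
#' @param path CSV path.
#' @return Frequency tibble.
#' @export
read_cancer_frequencies <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("arm", "gain_freq", "loss_freq")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("cancer frequency table missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  rng <- c(tab$gain_freq, tab$loss_freq)
  if (any(!is.finite(rng) | rng < 0 | rng > 1)) {
    stop("cancer frequencies must be in [0, 1].", call. = FALSE)
  }
  tab
}

#' Read a flagged-region table
#'
#' TSV with columns `chrom, start_bp, end_bp, label`, listing
#' pre-existing parental CNAs to exclude ("i" state) from sample calls.
#'
#' @param path TSV path.
#' @return Flag tibble.
#' @export
read_flags <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "start_bp", "end_bp")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("flag table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"label" %in% names(tab)) tab$label <- "flagged"
  tab
}
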