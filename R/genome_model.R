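#' Construct and validate a genome layout
#'
#' A genome layout is the coordinate frame for the whole pipeline: one row
#' per chromosome with its length, centromere interval, acrocentric flag,
#' and baseline copy number, plus a fixed bin size. All coordinates are
#' 0-based half-open (BED convention).
#'
#' @param chromosomes Data frame with columns `chrom`, `length`,
#'   `cen_start`, `cen_end`, optional `acrocentric` (0/1 or logical,
#'   default `FALSE`) and `baseline_cn` (integer copies, default 2; set
#'   per chromosome for sex chromosomes).
#' @param bin_size Bin width in bp (default 500000, i.e. 500 kb).
#' @return A tibble of class `genome_layout` with attribute `bin_size`.
#'   Chromosome order is the input row order.
#' @examples
#' layout <- toy_genome()
#' build_bin_grid(layout)
#' @export
genome_layout <- function(chromosomes, bin_size = 500000L) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    stop("`bin_size` must be a single positive number.", call. = FALSE)
  }
  need <- c("chrom", "length", "cen_start", "cen_end")
  miss <- setdiff(need, names(chromosomes))
  if (length(miss) > 0) {
    stop("layout is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lay <- tibble::as_tibble(chromosomes)
  if (!"acrocentric" %in% names(lay)) lay$acrocentric <- FALSE
  if (!"baseline_cn" %in% names(lay)) lay$baseline_cn <- 2L
  lay$acrocentric <- as.logical(lay$acrocentric)
  lay$chrom <- as.character(lay$chrom)
  if (anyDuplicated(lay$chrom)) {
    stop("duplicated chromosome names in layout.", call. = FALSE)
  }
  bad <- !(lay$cen_start > 0 & lay$cen_start < lay$cen_end &
             lay$cen_end < lay$length)
  if (any(bad)) {
    stop("centromere interval outside chromosome for: ",
         paste(lay$chrom[bad], collapse = ", "), call. = FALSE)
  }
  if (any(lay$baseline_cn < 0)) {
    stop("baseline_cn must be >= 0.", call. = FALSE)
  }
  lay <- lay[, c("chrom", "length", "cen_start", "cen_end",
                 "acrocentric", "baseline_cn")]
  structure(lay,
            bin_size = as.integer(bin_size),
            class = c("genome_layout", class(tibble::tibble())))
}

#' Bin size of a genome layout
#' @param layout A `genome_layout`.
#' @return Bin width in bp.
#' @export
bin_size <- function(layout) {
  bs <- attr(layout, "bin_size")
  if (is.null(bs)) stop("not a genome_layout: no bin_size attribute.",
                        call. = FALSE)
  bs
}

#' Read a genome layout from TSV or YAML
#'
#' TSV columns: `chrom`, `length`, `cen_start`, `cen_end`,
#' `acrocentric` (0/1), `baseline_cn`. A YAML file holds the same fields
#' under a `chromosomes` list plus an optional top-level `bin_size`.
#'
#' @param path File path (`.yaml`/`.yml` parsed as YAML, anything else
#'   as tab-separated text with a header).
#' @param bin_size Bin width in bp; for YAML a `bin_size` entry in the
#'   file takes precedence.
#' @return A `genome_layout`.
#' @export
read_genome_layout <- function(path, bin_size = 500000L) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    conf <- yaml::read_yaml(path)
    tab <- dplyr::bind_rows(lapply(conf$chromosomes, tibble::as_tibble))
    if (!is.null(conf$bin_size)) bin_size <- conf$bin_size
    return(genome_layout(tab, bin_size = bin_size))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genome_layout(tab, bin_size = bin_size)
}

#' Tile a genome layout into ordered bins
#'
#' Bins are half-open `[start, end)`, `bin_size` wide (last bin of a
#' chromosome may be shorter), sorted by chromosome order then start.
#' Each bin gets an arm label by comparing its midpoint with the
#' centromere midpoint. Bins overlapping the centromere interval are
#' masked, as are all p-arm bins of acrocentric chromosomes; masked bins
#' are excluded from segmentation and from burden denominators.
#'
#' @param layout A `genome_layout`.
#' @return Tibble with columns `chrom`, `start`, `end`, `bin`
#'   (0-based index within chromosome), `arm` ("p"/"q"), `masked`,
#'   `usable` (= `!masked`), `baseline_cn`.
#' @export
build_bin_grid <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  bs <- bin_size(layout)
  grid <- purrr::pmap_dfr(layout, function(chrom, length, cen_start,
                                           cen_end, acrocentric,
                                           baseline_cn) {
    starts <- seq(0, length - 1, by = bs)
    ends <- pmin(starts + bs, length)
    mid <- (starts + ends) / 2
    cen_mid <- (cen_start + cen_end) / 2
    arm <- ifelse(mid < cen_mid, "p", "q")
    masked <- (starts < cen_end & ends > cen_start) |
      (acrocentric & arm == "p")
    tibble::tibble(chrom = chrom, start = starts, end = ends,
                   bin = seq_along(starts) - 1L, arm = arm,
                   masked = masked, baseline_cn = baseline_cn)
  })
  grid$chrom <- factor(grid$chrom, levels = layout$chrom)
  grid <- dplyr::arrange(grid, .data$chrom, .data$start)
  grid$chrom <- as.character(grid$chrom)
  grid$usable <- !grid$masked
  grid
}

#' Usable-bin index within each chromosome
#'
#' Adds `uidx`, the 0-based index of each usable bin among the usable
#' bins of its chromosome (NA for masked bins). Segmentation and
#' breakpoint coordinates operate on this index.
#' @param grid Output of [build_bin_grid()].
#' @return `grid` with an extra `uidx` column.
#' @keywords internal
usable_index <- function(grid) {
  grid |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(uidx = ifelse(.data$usable,
                                cumsum(.data$usable) - 1L,
                                NA_integer_)) |>
    dplyr::ungroup()
}

#' A small synthetic test genome
#'
#' Four chromosomes of 30-60 bins at 500 kb with centromeres placed so
#' that both arms carry at least 15 usable bins on metacentric
#' chromosomes; `chrT4` is acrocentric (only its q arm is analyzed).
#' Intended for desk-scale tests and simulations without a full human
#' layout.
#'
#' @return A `genome_layout` with 164 usable bins.
#' @export
toy_genome <- function() {
  genome_layout(tibble::tibble(
    chrom = c("chrT1", "chrT2", "chrT3", "chrT4"),
    length = c(30e6, 22.5e6, 20e6, 15e6),
    cen_start = c(14.2e6, 10.1e6, 9.05e6, 1.5e6),
    cen_end = c(15.3e6, 11.0e6, 9.6e6, 2.0e6),
    acrocentric = c(FALSE, FALSE, FALSE, TRUE),
    baseline_cn = c(2L, 2L, 2L, 2L)
  ), bin_size = 500000L)
}

#' Bundled GRCh38-like human genome layout
#'
#' Convenience loader for the approximate human autosome + X layout
#' shipped with the package (chromosome lengths and centromere intervals
#' rounded to 0.1 Mb; acrocentric: 13, 14, 15, 21, 22). Suitable for
#' realistic-scale simulation, not for matching any specific external
#' bin grid.
#'
#' @param bin_size Bin width in bp (default 500 kb).
#' @return A `genome_layout`.
#' @export
human_genome <- function(bin_size = 500000L) {
  read_genome_layout(
    system.file("extdata", "grch38_layout.tsv", package = "cnadapt",
                mustWork = TRUE),
    bin_size = bin_size
  )
}
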