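#' Aneuploidy burden of a sample
#'
#' Fraction of the usable genome covered by qualifying gain/loss events.
#' Aneuploidy here means whole-chromosome and arm-level changes; focal
#' events enter the numerator only with `include_focal = TRUE`. Flagged
#' ("i") bins are excluded from numerator and denominator alike. The
#' computation is on the usable-bin grid (bins times bin size
#' approximates bp; the final bin of a chromosome may be shorter).
#'
#' @param calls A `cna_calls` object from [call_cna()], or a list with
#'   `segments` and `events` tibbles.
#' @param include_focal Count focal events too (default `FALSE`).
#' @return Tibble `sample_id, burden` (fraction in \[0, 1\]).
#' @export
aneuploidy_burden <- function(calls, include_focal = FALSE) {
  segments <- calls$segments
  events <- calls$events
  scopes <- c("whole_chromosome", "arm", if (include_focal) "focal")
  denom <- segments |>
    dplyr::filter(.data$state != "i") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(usable = sum(.data$n_bins), .groups = "drop")
  if (any(denom$usable == 0) || nrow(denom) == 0) {
    stop("burden undefined: no usable (non-ignored) bins.",
         call. = FALSE)
  }
  num <- events |>
    dplyr::filter(.data$scope %in% scopes) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(altered = sum(.data$span_bins), .groups = "drop")
  denom |>
    dplyr::left_join(num, by = "sample_id") |>
    dplyr::mutate(burden = dplyr::coalesce(.data$altered, 0L) /
                    .data$usable) |>
    dplyr::select("sample_id", "burden")
}

#' Per-arm gain/loss frequency table
#'
#' For each group (by default cell line x day), each chromosome arm, and
#' each direction: the percentage of populations carrying at least one
#' qualifying event on that arm. Whole-chromosome events count toward
#' both arms. Focal events are excluded unless `include_focal = TRUE`.
#'
#' @param events Event tibble (several samples; [classify_events()] /
#'   [call_cna()] output bound together) with a `sample_id` column.
#' @param metadata Cohort metadata with `sample_id`, grouping columns,
#'   and `population_id`.
#' @param layout A `genome_layout` (defines the arm universe).
#' @param group_by Metadata columns to group by (default
#'   `c("cell_line", "day")`).
#' @param include_focal Count focal events (default `FALSE`).
#' @return Tibble with the grouping columns plus `chrom, arm,
#'   direction, n_populations, n_with_event, pct` (0-100).
#' @export
frequency_table <- function(events, metadata, layout,
                            group_by = c("cell_line", "day"),
                            include_focal = FALSE) {
  grid <- build_bin_grid(layout)
  arm_universe <- grid |>
    dplyr::filter(.data$usable) |>
    dplyr::distinct(.data$chrom, .data$arm)
  scopes <- c("whole_chromosome", "arm", if (include_focal) "focal")
  ev <- events |>
    dplyr::filter(.data$scope %in% scopes) |>
    dplyr::inner_join(metadata, by = "sample_id")
  # expand whole-chromosome events to both usable arms
  ev_arm <- dplyr::bind_rows(
    ev |> dplyr::filter(.data$scope != "whole_chromosome"),
    ev |>
      dplyr::filter(.data$scope == "whole_chromosome") |>
      dplyr::select(-"arm") |>
      dplyr::inner_join(arm_universe, by = "chrom",
                        relationship = "many-to-many")
  )
  groups <- metadata |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c(group_by,
                                                  "population_id"))))
  sizes <- groups |>
    dplyr::count(dplyr::across(dplyr::all_of(group_by)),
                 name = "n_populations")
  if (any(sizes$n_populations == 0)) {
    warning("empty group skipped.", call. = FALSE)
  }
  shell <- sizes |>
    dplyr::cross_join(arm_universe) |>
    dplyr::cross_join(tibble::tibble(direction = c("gain", "loss")))
  hits <- ev_arm |>
    dplyr::distinct(dplyr::across(dplyr::all_of(
      c(group_by, "population_id", "chrom", "arm", "direction")))) |>
    dplyr::count(dplyr::across(dplyr::all_of(
      c(group_by, "chrom", "arm", "direction"))), name = "n_with_event")
  shell |>
    dplyr::left_join(hits, by = c(group_by, "chrom", "arm",
                                  "direction")) |>
    dplyr::mutate(n_with_event = dplyr::coalesce(.data$n_with_event, 0L),
                  pct = 100 * .data$n_with_event / .data$n_populations)
}

#' Proportions of whole-chromosome, arm, and focal CNAs
#'
#' Counts classified events (one event per maximal changed run) across
#' all samples within each day and normalizes to 100%. To view the
#' acrocentric-as-whole convention, classify the events with
#' `acrocentric_as_whole = TRUE` and pass those events instead.
#'
#' @param events Event tibble with `sample_id`.
#' @param metadata Metadata with `sample_id` and `day`.
#' @return Tibble `day, scope, n, pct`; all three scopes always present
#'   (zero rows filled in). Days without events give an all-zero row
#'   with a warning.
#' @export
cna_type_proportions <- function(events, metadata) {
  scopes <- c("whole_chromosome", "arm", "focal")
  days <- sort(unique(metadata$day))
  ev <- events |> dplyr::inner_join(metadata[, c("sample_id", "day")],
                                    by = "sample_id")
  out <- tidyr::expand_grid(day = days,
                            scope = factor(scopes, levels = scopes)) |>
    dplyr::left_join(
      ev |> dplyr::count(.data$day, .data$scope),
      by = c("day", "scope")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$day) |>
    dplyr::mutate(pct = if (sum(.data$n) > 0) {
      100 * .data$n / sum(.data$n)
    } else 0) |>
    dplyr::ungroup() |>
    dplyr::mutate(scope = as.character(.data$scope))
  if (any(tapply(out$n, out$day, sum) == 0)) {
    warning("day(s) with zero events: proportions reported as 0.",
            call. = FALSE)
  }
  out
}

#' Simple-regression F-test association
#'
#' Ordinary least squares `y = a + b x` with the overall F-test
#' `F = (SSR / 1) / (SSE / (n - 2))` and its upper-tail p-value on
#' (1, n-2) degrees of freedom — the test used for indicator-versus-
#' growth and indicator-versus-indicator comparisons (with binary `x`
#' this is a two-group comparison). A perfect fit (SSE = 0) reports
#' p = 0 with `perfect_fit = TRUE`.
#'
#' @param x Numeric or 0/1 indicator vector.
#' @param y Numeric response.
#' @return A `cna_ftest` object (use [generics::tidy()] /
#'   [generics::glance()] or `$` access: `slope, intercept, r_squared,
#'   statistic, p_value, n, slope_se, perfect_fit`).
#' @examples
#' fit <- association_ftest(rep(0:1, each = 10), rnorm(20))
#' glance(fit)
#' @export
association_ftest <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3 complete observations.", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("x has zero variance; association undefined.", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  ssr <- sum((stats::fitted(fit) - mean(y))^2)
  sst <- sse + ssr
  perfect <- sse <= 1e-12 * max(sst, 1e-300)
  if (perfect) {
    fstat <- Inf
    p <- 0
    se <- 0
  } else {
    fstat <- (ssr / 1) / (sse / (n - 2))
    p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
    se <- summary(fit)$coefficients["x", "Std. Error"]
  }
  structure(
    list(slope = unname(co[2]), intercept = unname(co[1]),
         r_squared = if (sst > 0) ssr / sst else NA_real_,
         statistic = fstat, p_value = p, n = n, slope_se = se,
         perfect_fit = perfect, fit = fit),
    class = "cna_ftest"
  )
}

#' @export
print.cna_ftest <- function(x, ...) {
  cat(sprintf(
    "OLS association (n = %d): slope = %.4g, R^2 = %.3f, F = %.4g, p = %.3g%s\n",
    x$n, x$slope, x$r_squared, x$statistic, x$p_value,
    if (x$perfect_fit) " [perfect fit]" else ""))
  invisible(x)
}

#' Build a population x region indicator matrix from events
#'
#' One row per population at the chosen day; one 0/1 column per
#' requested region. A region is written `"<chrom><arm>_<direction>"`
#' (e.g. `"chrT1q_gain"`) or `"<chrom>_<direction>"` to accept any arm
#' of the chromosome; whole-chromosome events count toward both arms.
#' Focal events count toward the arm they lie on when
#' `include_focal = TRUE`.
#'
#' @param events Event tibble with `sample_id`.
#' @param metadata Metadata with `sample_id, population_id, day`.
#' @param day Day to slice.
#' @param regions Character vector of region labels; default: all
#'   arm x direction combinations observed in `events` at that day.
#' @param include_focal Count focal events (default `FALSE`).
#' @return Tibble: `population_id` plus one integer column per region.
#' @export
event_indicator_matrix <- function(events, metadata, day,
                                   regions = NULL,
                                   include_focal = FALSE) {
  md <- metadata[metadata$day == day, ]
  scopes <- c("whole_chromosome", "arm", if (include_focal) "focal")
  ev <- events |>
    dplyr::inner_join(md[, c("sample_id", "population_id")],
                      by = "sample_id") |>
    dplyr::filter(.data$scope %in% scopes)
  labs_arm <- paste0(ev$chrom, ifelse(ev$scope == "whole_chromosome",
                                      "", ev$arm), "_", ev$direction)
  labs_chrom <- paste0(ev$chrom, "_", ev$direction)
  if (is.null(regions)) {
    regions <- sort(unique(labs_arm))
  }
  out <- tibble::tibble(population_id = sort(unique(md$population_id)))
  for (r in regions) {
    whole_lab <- sub("^([^_]*[0-9A-Za-z])[pq]_", "\\1_", r)
    hit <- labs_arm == r |
      (ev$scope == "whole_chromosome" & labs_chrom == whole_lab) |
      labs_chrom == r
    pops <- unique(ev$population_id[hit])
    out[[r]] <- as.integer(out$population_id %in% pops)
  }
  out
}

#' Pairwise aneuploidy co-occurrence / exclusivity scan
#'
#' For each requested pair of indicator columns, runs
#' [association_ftest()] of one indicator on the other and tabulates
#' the 2x2 co-occurrence counts. Degenerate indicators (all 0 or all 1)
#' are skipped with a reason.
#'
#' @param indicators Output of [event_indicator_matrix()] (or any tibble
#'   of 0/1 columns keyed by `population_id`).
#' @param pairs Tibble with columns `a`, `b` naming indicator columns;
#'   default all unordered pairs.
#' @return Tibble `a, b, n, slope, statistic, p_value, n00, n01, n10,
#'   n11, skipped, reason`.
#' @export
anticorrelation_scan <- function(indicators, pairs = NULL) {
  cols <- setdiff(names(indicators), "population_id")
  if (is.null(pairs)) {
    if (length(cols) < 2) stop("need at least two indicator columns.",
                               call. = FALSE)
    cmb <- utils::combn(cols, 2)
    pairs <- tibble::tibble(a = cmb[1, ], b = cmb[2, ])
  }
  purrr::pmap(pairs[, c("a", "b")], function(a, b) {
    x <- indicators[[a]]
    y <- indicators[[b]]
    base <- tibble::tibble(
      a = a, b = b, n = length(x),
      n00 = sum(x == 0 & y == 0), n01 = sum(x == 0 & y == 1),
      n10 = sum(x == 1 & y == 0), n11 = sum(x == 1 & y == 1))
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      deg <- if (length(unique(x)) < 2) a else b
      return(dplyr::mutate(base, slope = NA_real_,
                           statistic = NA_real_, p_value = NA_real_,
                           skipped = TRUE,
                           reason = paste0("degenerate indicator: ", deg)))
    }
    ft <- association_ftest(x, y)
    dplyr::mutate(base, slope = ft$slope, statistic = ft$statistic,
                  p_value = ft$p_value, skipped = FALSE,
                  reason = NA_character_)
  }) |>
    purrr::list_rbind() |>
    dplyr::relocate("a", "b", "n", "slope", "statistic", "p_value")
}

#' Correlate adapted-cohort arm frequencies with cancer frequencies
#'
#' The adapted per-arm frequency is the unweighted mean over cell lines
#' of the per-cell-line frequencies (fractions of populations with the
#' event); it is compared with an external cancer arm-frequency table by
#' Pearson correlation and the regression F-test, gains and losses
#' separately.
#'
#' @param adapted [frequency_table()] output (one day), grouped by cell
#'   line; arm labels are formed as `paste0(chrom, arm)`.
#' @param cancer Cancer table from [read_cancer_frequencies()]
#'   (fractions in \[0, 1\]; pooled or one cancer type).
#' @param direction `"gain"` or `"loss"`.
#' @return One-row tibble `direction, n_arms, r, slope, statistic,
#'   p_value`.
#' @export
cancer_frequency_correlation <- function(adapted, cancer,
                                         direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  adap <- adapted |>
    dplyr::filter(.data$direction == .env$direction) |>
    dplyr::mutate(arm_label = paste0(.data$chrom, .data$arm)) |>
    dplyr::group_by(.data$arm_label) |>
    dplyr::summarise(freq = mean(.data$pct) / 100, .groups = "drop")
  ccol <- if (direction == "gain") "gain_freq" else "loss_freq"
  canc <- cancer |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(cancer_freq = mean(.data[[ccol]]),
                     .groups = "drop")
  unmatched <- setdiff(adap$arm_label, canc$arm)
  if (length(unmatched) > 0) {
    stop("arms missing from the cancer table: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  both <- dplyr::inner_join(adap, canc,
                            by = c("arm_label" = "arm"))
  if (nrow(both) < 10) {
    stop("need >= 10 shared arms, got ", nrow(both), call. = FALSE)
  }
  ft <- association_ftest(both$cancer_freq, both$freq)
  tibble::tibble(direction = direction, n_arms = nrow(both),
                 r = stats::cor(both$cancer_freq, both$freq),
                 slope = ft$slope, statistic = ft$statistic,
                 p_value = ft$p_value)
}
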