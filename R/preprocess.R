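#' GC-bias correction of binned counts
#'
#' Low-coverage WGS bin counts depend smoothly on local GC content. The
#' correction models the expected count as a smooth function of GC — a
#' natural-spline quasi-Poisson regression on a log link — and divides
#' each count by the fitted factor, rescaling so the genome-wide median
#' corrected count equals the genome-wide median raw count.
#'
#' The fit is copy-number aware: a first pass estimates the curve on all
#' usable bins and scores every chromosome arm against the genome's
#' dominant arm level (the median of per-arm medians, so one large
#' aneuploid chromosome cannot drag the reference); the curve is then
#' refit using only bins of arms within 10% of that level. Without this
#' step, an altered arm whose bins happen to occupy one end of the GC
#' range is partially absorbed into the GC curve (copy number and GC
#' are confounded in a single sample). A global regression rather than
#' a scatterplot smoother keeps the fit stable at sparse GC extremes.
#'
#' @param profile Profile tibble with `count` and `gc` (one or more
#'   samples; corrected per sample).
#' @param layout A `genome_layout` (defines usable bins for the fit).
#' @param df Spline degrees of freedom (default 4).
#' @return The profile with a `corrected` column.
#' @export
correct_gc <- function(profile, layout, df = 4) {
  grid <- build_bin_grid(layout)
  armkey <- paste(grid$chrom, grid$arm)
  if (!"sample_id" %in% names(profile)) profile$sample_id <- "sample"
  profile |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(p, key) {
      p <- dplyr::arrange(p, match(.data$chrom, layout$chrom), .data$start)
      u <- grid$usable
      if (sum(u) < 100) {
        stop("GC correction needs >= 100 usable bins, got ", sum(u),
             call. = FALSE)
      }
      if (stats::sd(p$gc[u]) == 0) {
        warning("constant GC: correction skipped for ",
                key$sample_id[1], call. = FALSE)
        p$corrected <- p$count
        return(p)
      }
      fit_curve <- function(sel) {
        basis <- splines::ns(p$gc[sel], df = df)
        fit <- stats::glm(p$count[sel] ~ basis,
                          family = stats::quasipoisson())
        eta <- cbind(1, stats::predict(basis, p$gc)) %*% stats::coef(fit)
        pmax(exp(eta)[, 1], 1e-9)
      }
      c0 <- p$count / fit_curve(u)
      arm_med <- vapply(unique(armkey[u]), function(a) {
        stats::median(c0[u & armkey == a])
      }, numeric(1))
      ref_level <- stats::median(arm_med)   # dominant arm level
      if (!is.finite(ref_level) || ref_level <= 0) {
        stop("median corrected count is zero; profile too sparse.",
             call. = FALSE)
      }
      near <- names(arm_med)[abs(arm_med / ref_level - 1) < 0.1]
      keep <- u & armkey %in% near
      if (sum(keep) < max(60, 15 * df)) keep <- u
      corrected <- p$count / fit_curve(keep)
      med_raw <- stats::median(p$count[u])
      med_cor <- stats::median(corrected[u])
      if (med_cor <= 0) {
        stop("median corrected count is zero; profile too sparse.",
             call. = FALSE)
      }
      p$corrected <- corrected * med_raw / med_cor
      p
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("sample_id")
}

#' Normalize corrected counts to population-average copy number
#'
#' Scales each sample's GC-corrected counts onto an absolute copies
#' scale (2 = disomic at a diploid baseline):
#' `cn_i = corrected_i / anchor * median(baseline_cn)`. With
#' `anchor = "euploid_arms"` (default) the anchor is the median
#' corrected count over bins of arms whose rounded copy state equals
#' the baseline; anchoring on the euploid portion avoids the slight
#' scale inflation a plain genome-wide median suffers when a minority
#' of bins is altered. `anchor = "median"` uses the plain genome-wide
#' median, which keeps disomic regions at ~2 only while fewer than
#' half of the usable bins are altered. Downstream state calling is
#' differential (sample minus parental), which cancels shared anchor
#' error. When a reference profile with `cn` is supplied, a per-bin
#' `ratio` track (`cn / ref_cn`) is added for diagnostics.
#'
#' @param profile Profile tibble with a `corrected` column (see
#'   [correct_gc()]); multiple samples allowed.
#' @param layout A `genome_layout`.
#' @param reference Optional single-sample profile with `cn`, matched by
#'   bin.
#' @param anchor `"euploid_arms"` (default) or `"median"`.
#' @return The profile with a `cn` column (and `ratio` if `reference`).
#' @export
normalize_to_copy_number <- function(profile, layout, reference = NULL,
                                     anchor = c("euploid_arms",
                                                "median")) {
  anchor <- match.arg(anchor)
  grid <- build_bin_grid(layout)
  armkey <- paste(grid$chrom, grid$arm)
  if (!"corrected" %in% names(profile)) {
    stop("profile has no `corrected` column; run correct_gc() first.",
         call. = FALSE)
  }
  if (!"sample_id" %in% names(profile)) profile$sample_id <- "sample"
  base_cn <- stats::median(grid$baseline_cn[grid$usable])
  out <- profile |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(p, key) {
      p <- dplyr::arrange(p, match(.data$chrom, layout$chrom), .data$start)
      u <- grid$usable
      med <- stats::median(p$corrected[u])
      if (!is.finite(med) || med <= 0) {
        stop("median corrected count is zero for ", key$sample_id[1],
             call. = FALSE)
      }
      if (anchor == "euploid_arms") {
        # anchor on arms sitting within 10% of the dominant arm level
        # (median of per-arm medians, baseline-adjusted); a plain
        # genome-wide median drifts when a sizable minority of bins is
        # altered, and rounding to integer states would let subclonal
        # (non-integer) arms leak into the anchor
        arms <- unique(armkey[u])
        rel <- vapply(arms, function(a) {
          grid$baseline_cn[u & armkey == a][1] / base_cn
        }, numeric(1))
        arm_med <- vapply(arms, function(a) {
          stats::median(p$corrected[u & armkey == a])
        }, numeric(1)) / rel
        ref_level <- stats::median(arm_med[rel > 0])
        near <- arms[rel > 0 & abs(arm_med / ref_level - 1) < 0.1]
        if (length(near) > 0) {
          sel <- u & armkey %in% near
          med <- stats::median(p$corrected[sel] /
                                 rel[match(armkey[sel], arms)])
        }
      }
      p$cn <- p$corrected / med * base_cn
      p
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("sample_id")
  if (!is.null(reference)) {
    if (!"cn" %in% names(reference)) {
      stop("reference profile has no `cn` column.", call. = FALSE)
    }
    ref <- dplyr::arrange(reference, match(.data$chrom, layout$chrom),
                          .data$start)
    out <- out |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(ratio = .data$cn / ifelse(ref$cn > 0, ref$cn, NA)) |>
      dplyr::ungroup()
  }
  out
}

#' Preprocess a raw binned profile to copy number
#'
#' Convenience wrapper: [correct_gc()] then
#' [normalize_to_copy_number()].
#'
#' @inheritParams correct_gc
#' @return Profile with `corrected` and `cn` columns.
#' @export
preprocess_profile <- function(profile, layout, df = 4) {
  normalize_to_copy_number(correct_gc(profile, layout, df = df), layout)
}
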