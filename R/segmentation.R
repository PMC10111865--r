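#' Robust noise variance for change-in-mean segmentation
#'
#' Estimated from lag-1 differences, `(MAD(diff(x)) / sqrt(2))^2`, which
#' is insensitive to the mean shifts themselves.
#'
#' @param x Numeric vector.
#' @return Variance estimate (may be 0 for (near-)constant input).
#' @export
estimate_sigma2 <- function(x) {
  if (length(x) < 2) return(0)
  (stats::mad(diff(x)) / sqrt(2))^2
}

# Gaussian change-in-mean cost of x[(s+1):t] for 0-based boundaries s < t,
# normalized by sigma2. Vectorized over s. cs/cs2 are c(0, cumsum(x)) etc.
seg_cost <- function(s, t, cs, cs2, sigma2) {
  len <- t - s
  sx <- cs[t + 1] - cs[s + 1]
  sx2 <- cs2[t + 1] - cs2[s + 1]
  pmax(sx2 - sx^2 / len, 0) / sigma2
}

# Shared tie-break: among candidate total costs, prefer minimal cost
# (within a relative tolerance), then fewer change points, then the
# earliest last-change-point. Returns the index of the chosen candidate.
choose_candidate <- function(costs, n_cp, starts) {
  cmin <- min(costs)
  tol <- 1e-9 * (1 + abs(cmin))
  ok <- which(costs <= cmin + tol)
  ok <- ok[n_cp[ok] == min(n_cp[ok])]
  ok[which.min(starts[ok])]
}

segmentation_result <- function(x, cps, penalty, sigma2, cost) {
  n <- length(x)
  bounds <- c(0L, cps, n)
  segs <- tibble::tibble(
    start = bounds[-length(bounds)],
    end = bounds[-1]
  )
  segs$n_bins <- segs$end - segs$start
  segs$mean <- vapply(seq_len(nrow(segs)), function(i) {
    mean(x[(segs$start[i] + 1):segs$end[i]])
  }, numeric(1))
  structure(
    list(changepoints = as.integer(cps), n = n, penalty = penalty,
         sigma2 = sigma2, cost = cost, segments = segs),
    class = "cna_changepoints"
  )
}

#' @export
print.cna_changepoints <- function(x, ...) {
  cat("Change-point fit: n =", x$n, "| penalty =",
      format(x$penalty, digits = 4), "| sigma2 =",
      format(x$sigma2, digits = 4), "\n")
  cat("Change points (0-based boundaries):",
      if (length(x$changepoints) == 0) "none"
      else paste(x$changepoints, collapse = ", "), "\n")
  print(x$segments, ...)
  invisible(x)
}

#' Exact change-point detection by PELT
#'
#' Minimizes the penalized Gaussian change-in-mean cost
#' `sum_j C(segment_j) + penalty * m`, with
#' `C(seg) = sum((x - mean(seg))^2) / sigma2` and `m` the number of
#' change points, over all segmentations with segments of at least
#' `min_seg` points. PELT prunes candidate split points but returns the
#' same optimum as exhaustive optimal partitioning
#' ([optimal_partitioning()]). Ties are broken toward fewer change
#' points, then the earliest boundaries, so results are deterministic.
#'
#' @param values Numeric series (binned copy numbers of one chromosome).
#' @param penalty Per-change-point penalty on the normalized-cost scale;
#'   default `2 * log(n)` (the BIC-like choice; equal to
#'   `2 * sigma2 * log(n)` on the un-normalized scale).
#' @param min_seg Minimum segment length in points (default 2).
#' @param sigma2 Noise variance; default [estimate_sigma2()].
#' @return A `cna_changepoints` object: change points as 0-based
#'   boundary indices in `(0, n)`, the penalty and variance used, the
#'   achieved cost (`sum of segment costs + penalty * m`), and a
#'   segment tibble with per-segment means.
#' @examples
#' pelt(c(rnorm(30), rnorm(30, 4)))
#' @export
pelt <- function(values, penalty = NULL, min_seg = 2L, sigma2 = NULL) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite.", call. = FALSE)
  n <- length(x)
  min_seg <- as.integer(min_seg)
  if (min_seg < 1) stop("min_seg must be >= 1.", call. = FALSE)
  if (is.null(sigma2)) sigma2 <- estimate_sigma2(x)
  if (is.null(penalty)) penalty <- 2 * log(max(n, 2))
  if (penalty < 0) stop("penalty must be >= 0.", call. = FALSE)
  if (n < 2 * min_seg || sigma2 <= 0) {
    # no admissible split (or an exactly flat series): one segment
    cost <- if (n > 0 && sigma2 > 0) {
      cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
      seg_cost(0L, n, cs, cs2, sigma2)
    } else 0
    return(segmentation_result(x, integer(0), penalty,
                               sigma2, cost))
  }
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  f <- rep(Inf, n + 1)         # f[s + 1] = optimal cost of x[1:s] (+pen)
  f[1] <- -penalty
  ncp <- integer(n + 1)
  prev <- rep(NA_integer_, n + 1)
  cand <- 0L                   # candidate boundaries (0-based)
  # Pruning is delayed by min_seg steps: a candidate dominated at time t
  # is only provably dominated for t' >= t + min_seg (the comparison
  # path through t needs an admissible segment (t, t']), so it stays
  # usable inside that window. prune_at[s + 1] holds its removal time.
  prune_at <- rep(Inf, n + 1)
  for (t in seq(min_seg, n)) {
    cand <- cand[prune_at[cand + 1] > t]
    el <- cand[t - cand >= min_seg]
    if (length(el) == 0) next
    base <- f[el + 1] + seg_cost(el, t, cs, cs2, sigma2)
    tot <- base + penalty
    best <- choose_candidate(tot, ncp[el + 1], el)
    f[t + 1] <- tot[best]
    prev[t + 1] <- el[best]
    ncp[t + 1] <- ncp[el[best] + 1] + 1L
    # mark dominated boundaries for removal after the safety window
    dominated <- el[base > f[t + 1] + 1e-9 * (1 + abs(f[t + 1]))]
    prune_at[dominated + 1] <- pmin(prune_at[dominated + 1],
                                    t + min_seg)
    cand <- c(cand, t)
  }
  cps <- integer(0)
  b <- n
  while (!is.na(prev[b + 1]) && prev[b + 1] > 0) {
    b <- prev[b + 1]
    cps <- c(b, cps)
  }
  segmentation_result(x, cps, penalty, sigma2, f[n + 1])
}

#' Exhaustive optimal partitioning (test oracle)
#'
#' The O(n^2) dynamic program over all admissible segmentations, with no
#' pruning; identical cost model and tie-breaking as [pelt()]. Used as
#' the independent oracle establishing PELT's exactness.
#'
#' @inheritParams pelt
#' @return A `cna_changepoints` object.
#' @export
optimal_partitioning <- function(values, penalty = NULL, min_seg = 2L,
                                 sigma2 = NULL) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite.", call. = FALSE)
  n <- length(x)
  if (n > 2000) stop("oracle limited to n <= 2000.", call. = FALSE)
  min_seg <- as.integer(min_seg)
  if (is.null(sigma2)) sigma2 <- estimate_sigma2(x)
  if (is.null(penalty)) penalty <- 2 * log(max(n, 2))
  if (n < 2 * min_seg || sigma2 <= 0) {
    cost <- if (n > 0 && sigma2 > 0) {
      cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
      seg_cost(0L, n, cs, cs2, sigma2)
    } else 0
    return(segmentation_result(x, integer(0), penalty, sigma2, cost))
  }
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  f <- rep(Inf, n + 1)
  f[1] <- -penalty
  ncp <- integer(n + 1)
  prev <- rep(NA_integer_, n + 1)
  for (t in seq(min_seg, n)) {
    el <- c(0L, seq_len(t - min_seg))
    el <- el[is.finite(f[el + 1])]
    el <- el[el == 0L | el >= min_seg]
    if (length(el) == 0) next
    tot <- f[el + 1] + seg_cost(el, t, cs, cs2, sigma2) + penalty
    best <- choose_candidate(tot, ncp[el + 1], el)
    f[t + 1] <- tot[best]
    prev[t + 1] <- el[best]
    ncp[t + 1] <- ncp[el[best] + 1] + 1L
  }
  cps <- integer(0)
  b <- n
  while (!is.na(prev[b + 1]) && prev[b + 1] > 0) {
    b <- prev[b + 1]
    cps <- c(b, cps)
  }
  segmentation_result(x, cps, penalty, sigma2, f[n + 1])
}

#' Segment one chromosome of a normalized profile
#'
#' Runs [pelt()] on the chromosome's usable bins (q-arm only for
#' acrocentric chromosomes). Change points are detected on the
#' square-root of the copy-number track: bin-count noise grows with
#' copy number, and the square root approximately stabilizes the
#' variance so one global noise estimate applies to altered and
#' unaltered regions alike. Segment means are reported on the copies
#' scale.
#'
#' If at least one change point is found anywhere in the chromosome,
#' the chromosome is split additionally at the centromere, so that
#' focal and arm-level changes can be distinguished downstream; the
#' split is applied by re-running the detection on each arm separately
#' with the centromere as a forced boundary. Re-segmenting (rather than
#' merely inserting the cut into the genome-wide solution) prevents a
#' change point that sits a bin or two off the true arm boundary from
#' leaving a stray fragment next to the centromere: within a single
#' arm such a fragment no longer pays for its penalty and disappears.
#' A chromosome without change points stays a single segment spanning
#' both arms.
#'
#' @param profile Single-sample profile with `cn` (see
#'   [normalize_to_copy_number()]).
#' @param layout A `genome_layout`.
#' @param chrom Chromosome name.
#' @param penalty Per-change-point penalty; default `3 * log(n)` of the
#'   series being segmented. The pipeline default is deliberately
#'   stiffer than the textbook BIC factor of 2: the per-chromosome
#'   series are short, the noise variance is estimated, and the
#'   downstream one-to-one alignment and strict arm definitions are
#'   sensitive to over-segmentation, so the penalty is calibrated to
#'   keep spurious fragments rare on simulated flat profiles.
#' @param min_seg,sigma2 Passed to [pelt()].
#' @return Segment tibble: `sample_id, chrom, arm, start_bin, end_bin`
#'   (0-based half-open on the chromosome's usable-bin index),
#'   `start_bp, end_bp, n_bins, mean_cn`. Zero usable bins give an
#'   empty tibble with a warning.
#' @export
segment_chromosome <- function(profile, layout, chrom, penalty = NULL,
                               min_seg = 2L, sigma2 = NULL) {
  ub <- usable_bins(profile, layout)
  ub <- ub[ub$chrom == chrom, ]
  sid <- if ("sample_id" %in% names(profile)) profile$sample_id[1] else "sample"
  if (nrow(ub) == 0) {
    warning("chromosome ", chrom, " has zero usable bins.", call. = FALSE)
    return(empty_segments())
  }
  pen <- function(n) {
    if (is.null(penalty)) 3 * log(max(n, 2)) else penalty
  }
  fit <- pelt(sqrt(ub$cn), penalty = pen(nrow(ub)), min_seg = min_seg,
              sigma2 = sigma2)
  cps <- fit$changepoints
  cen <- centromere_boundary(ub)
  if (length(cps) > 0 && !is.na(cen)) {
    # centromere split: re-detect per arm under the forced boundary
    fit_p <- pelt(sqrt(ub$cn[seq_len(cen)]), penalty = pen(cen),
                  min_seg = min_seg, sigma2 = sigma2)
    fit_q <- pelt(sqrt(ub$cn[(cen + 1):nrow(ub)]),
                  penalty = pen(nrow(ub) - cen),
                  min_seg = min_seg, sigma2 = sigma2)
    cps <- sort(unique(c(fit_p$changepoints, cen,
                         fit_q$changepoints + cen)))
  }
  cut_segments(ub, cps, sid)
}

#' Global noise variance of a normalized profile
#'
#' Estimated on the variance-stabilized (square-root) copy-number
#' track used for change-point detection: lag-1 differences are taken
#' within each chromosome's usable bins and pooled genome-wide before
#' the MAD-based estimate. Pooling gives a far more stable estimate
#' than per-chromosome estimation, and the MAD of differences is
#' unaffected by the (sparse) true change points.
#'
#' @param profile Single-sample profile with `cn`.
#' @param layout A `genome_layout`.
#' @return Variance estimate on the square-root scale.
#' @export
profile_sigma2 <- function(profile, layout) {
  ub <- usable_bins(profile, layout)
  d <- unlist(lapply(split(sqrt(ub$cn), ub$chrom), diff),
              use.names = FALSE)
  if (length(d) < 2) return(0)
  (stats::mad(d) / sqrt(2))^2
}

#' Segment every chromosome of one or more samples
#'
#' The noise variance is estimated once per sample, genome-wide
#' ([profile_sigma2()]), and shared by the per-chromosome [pelt()] runs;
#' the penalty stays per-chromosome (`2 log n` by default).
#'
#' @param profile Profile tibble with `cn` (multiple samples allowed).
#' @param layout A `genome_layout`.
#' @param penalty,min_seg Passed to [pelt()] per chromosome.
#' @param sigma2 Noise variance; default genome-wide per sample.
#' @return Segment tibble as in [segment_chromosome()], all chromosomes
#'   and samples bound together.
#' @export
segment_profile <- function(profile, layout, penalty = NULL,
                            min_seg = 2L, sigma2 = NULL) {
  if (!"sample_id" %in% names(profile)) profile$sample_id <- "sample"
  profile |>
    dplyr::group_split(.data$sample_id) |>
    purrr::map(function(p) {
      s2 <- if (is.null(sigma2)) profile_sigma2(p, layout) else sigma2
      purrr::map(layout$chrom, function(ch) {
        suppressWarnings(
          segment_chromosome(p, layout, ch, penalty = penalty,
                             min_seg = min_seg, sigma2 = s2)
        )
      }) |> purrr::list_rbind()
    }) |>
    purrr::list_rbind()
}

# ---- internal helpers on the usable-bin index ------------------------------

# Per-chromosome usable bins of a single-sample profile, with uidx and cn.
usable_bins <- function(profile, layout) {
  grid <- usable_index(build_bin_grid(layout))
  p <- dplyr::arrange(profile, match(.data$chrom, layout$chrom),
                      .data$start)
  if (nrow(p) != nrow(grid)) {
    stop("profile does not match the layout grid.", call. = FALSE)
  }
  if (!"cn" %in% names(p)) {
    stop("profile has no `cn` column; normalize first.", call. = FALSE)
  }
  grid$cn <- p$cn
  grid[grid$usable, c("chrom", "start", "end", "arm", "uidx", "cn")]
}

# Usable-bin boundary index of the centromere (first q bin), NA when a
# chromosome has a single usable arm.
centromere_boundary <- function(ub) {
  nq <- sum(ub$arm == "q")
  np <- sum(ub$arm == "p")
  if (np == 0 || nq == 0) return(NA_integer_)
  np
}

empty_segments <- function() {
  tibble::tibble(sample_id = character(), chrom = character(),
                 arm = character(), start_bin = integer(),
                 end_bin = integer(), start_bp = double(),
                 end_bp = double(), n_bins = integer(),
                 mean_cn = double())
}

# Cut one chromosome's usable bins at 0-based boundaries cps.
cut_segments <- function(ub, cps, sample_id) {
  n <- nrow(ub)
  bounds <- c(0L, as.integer(cps), n)
  purrr::map(seq_len(length(bounds) - 1), function(i) {
    idx <- (bounds[i] + 1):bounds[i + 1]
    arms <- unique(ub$arm[idx])
    tibble::tibble(
      sample_id = sample_id,
      chrom = ub$chrom[1],
      arm = if (length(arms) == 1) arms else "pq",
      start_bin = bounds[i],
      end_bin = bounds[i + 1],
      start_bp = ub$start[idx[1]],
      end_bp = ub$end[idx[length(idx)]],
      n_bins = length(idx),
      mean_cn = mean(ub$cn[idx])
    )
  }) |> purrr::list_rbind()
}
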