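#' Draw per-bin GC fractions for a genome
#'
#' GC content is a property of the genome, not of a sample: one draw is
#' shared by every profile simulated on the same layout, so that GC
#' correction can cancel the bias by construction. Values follow a
#' beta-shaped distribution rescaled to \[0.3, 0.6\] (typical mammalian
#' 500-kb bins).
#'
#' @param layout A `genome_layout`.
#' @return Numeric vector of GC fractions, one per bin of the grid.
#' @export
simulate_gc <- function(layout) {
  grid <- build_bin_grid(layout)
  0.3 + 0.3 * stats::rbeta(nrow(grid), 5, 5)
}

#' Build an integer karyotype from an event list
#'
#' Events modify the baseline copy number additively; overlapping events
#' compose (a whole-chromosome gain plus a focal loss inside it returns
#' the focal interval to baseline).
#'
#' @param layout A `genome_layout`.
#' @param events Tibble with columns `chrom`, `region` (`"whole"`,
#'   `"p"`, `"q"`, or `"interval"`), `delta` (integer copy change) and,
#'   for intervals, `start_bp`, `end_bp`. `NULL` or empty means
#'   baseline everywhere.
#' @return Bin grid tibble with an integer `cn` column (one subclone's
#'   karyotype).
#' @export
simulate_karyotype <- function(layout, events = NULL) {
  grid <- build_bin_grid(layout)
  grid$cn <- as.numeric(grid$baseline_cn)
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      if (!ev$chrom %in% layout$chrom) {
        stop("event references unknown chromosome: ", ev$chrom,
             call. = FALSE)
      }
      hit <- grid$chrom == ev$chrom
      hit <- hit & switch(
        ev$region,
        whole = TRUE,
        p = grid$arm == "p",
        q = grid$arm == "q",
        interval = grid$start < ev$end_bp & grid$end > ev$start_bp,
        stop("unknown region type: ", ev$region, call. = FALSE)
      )
      grid$cn[hit] <- grid$cn[hit] + ev$delta
    }
  }
  if (any(grid$cn < 0)) {
    stop("event list produces negative copy numbers.", call. = FALSE)
  }
  grid
}

#' Simulate a binned read-count profile
#'
#' Counts are negative-binomial draws around an expectation proportional
#' to the population-average copy number times a smooth GC bias:
#' `E[count_i] = mean_reads * (cn_i / mean(cn)) * bias(gc_i) / mean(bias)`
#' with `bias(gc) = b0 + b1 * z + b2 * z^2`, `z = gc - 0.45`, floored at
#' 0.05. The population-average copy number is the fraction-weighted
#' mean over subclone karyotypes, so subclonal events yield non-integer
#' expected copies. `dispersion` is the negative-binomial size
#' parameter (Poisson limit as it grows).
#'
#' @param layout A `genome_layout`.
#' @param karyotypes One karyotype (from [simulate_karyotype()]) or a
#'   list of subclone karyotypes.
#' @param fractions Subclone fractions summing to 1 (default a single
#'   clone).
#' @param mean_reads Mean reads per usable bin (default 50).
#' @param dispersion Negative-binomial size (default 100).
#' @param gc Per-bin GC fractions (see [simulate_gc()]); required.
#' @param gc_bias Quadratic bias coefficients `c(b0, b1, b2)`; the
#'   default `c(1, 1.2, -5)` spans a ~1.5-fold max/min range over
#'   GC 0.3-0.6. Use `c(1, 0, 0)` for no bias.
#' @param sample_id Sample name.
#' @return A binned profile tibble (`sample_id, chrom, start, end,
#'   count, gc`) with the true average copy number in `cn_true`.
#' @export
simulate_profile <- function(layout, karyotypes, fractions = 1,
                             mean_reads = 50, dispersion = 100,
                             gc = NULL, gc_bias = c(1, 1.2, -5),
                             sample_id = "sample") {
  if (is.null(gc)) {
    stop("supply per-genome `gc` (simulate_gc) so bias is shared ",
         "across samples.", call. = FALSE)
  }
  if (mean_reads <= 0) stop("mean_reads must be > 0.", call. = FALSE)
  if (inherits(karyotypes, "data.frame")) karyotypes <- list(karyotypes)
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("subclone fractions must sum to 1.", call. = FALSE)
  }
  grid <- build_bin_grid(layout)
  cn_avg <- Reduce(`+`, purrr::map2(karyotypes, fractions,
                                    function(k, f) f * k$cn))
  z <- gc - 0.45
  bias <- pmax(gc_bias[1] + gc_bias[2] * z + gc_bias[3] * z^2, 0.05)
  u <- grid$usable
  mu <- mean_reads * (cn_avg / mean(cn_avg[u])) *
    bias / mean(bias[u])
  counts <- stats::rnbinom(length(mu), mu = mu, size = dispersion)
  tibble::tibble(
    sample_id = sample_id, chrom = grid$chrom, start = grid$start,
    end = grid$end, count = counts, gc = gc, cn_true = cn_avg
  )
}

#' Default region set for cohort simulation
#'
#' Planted alteration regions on the toy genome, with per-day population
#' frequencies shaped like an adaptation time course: whole-chromosome
#' changes dominate early and are refined toward arm and focal changes
#' at later time points (whole-chromosome share above 60% at day 30,
#' focal share roughly doubling from day 30 to day 90). `group`ed rows
#' are mutually exclusive within a population-day (at most one region of
#' a group is present, e.g. a whole-chromosome event replaced by its arm
#' counterpart later on).
#'
#' @param layout A `genome_layout` (defaults to [toy_genome()]; regions
#'   reference its chromosomes).
#' @return Tibble `region_id, chrom, region, delta, clone_fraction,
#'   group, beta` plus frequency columns `f0, f30, f60, f90`.
#' @export
default_cohort_regions <- function(layout = toy_genome()) {
  ch <- layout$chrom
  tibble::tribble(
    ~region_id,   ~chrom, ~region,    ~delta, ~clone_fraction, ~group, ~beta,
    "c1_whole_g", ch[1],  "whole",    1L,     1,               "g1",   0.04,
    "c1_q_g",     ch[1],  "q",        1L,     1,               "g1",   0.04,
    "c2_whole_l", ch[2],  "whole",    -1L,    1,               "g2",   0.05,
    "c2_p_l",     ch[2],  "p",        -1L,    1,               "g2",   0.05,
    "c3_q_focal", ch[3],  "interval", -1L,    1,               NA,     0.00,
    "c4_q_l",     ch[4],  "q",        -1L,    1,               NA,     0.03
  ) |>
    dplyr::mutate(
      start_bp = ifelse(.data$region == "interval", 12e6, NA),
      end_bp = ifelse(.data$region == "interval", 20e6, NA),
      f0 = 0,
      f30 = c(0.55, 0.05, 0.45, 0.05, 0.10, 0.35),
      f60 = c(0.40, 0.25, 0.35, 0.20, 0.20, 0.55),
      f90 = c(0.25, 0.45, 0.20, 0.40, 0.30, 0.80)
    )
}

#' Simulate an adaptation cohort with known ground truth
#'
#' Generates one matched parental (wild-type) profile plus one profile
#' per population and day. For each population-day, each region is
#' present with its day-specific frequency; rows sharing a `group` are
#' mutually exclusive (one of them is chosen with probability
#' proportional to its frequency), which models a whole-chromosome event
#' being replaced by its arm-level refinement. Growth is
#' `growth_plus_rev = baseline + sum(beta * indicator) + N(0, sd)`,
#' normalized to the untreated parental line; `growth_minus_rev` is
#' noise around 1. Trajectories are inputs (frequencies per day), not
#' the output of an explicit population-genetics model.
#'
#' @param layout A `genome_layout`.
#' @param regions Region table as in [default_cohort_regions()]
#'   (columns `region_id, chrom, region, delta, clone_fraction, group,
#'   beta, start_bp, end_bp` and `f<day>` frequency columns).
#' @param n_populations Number of independent populations (default 20).
#' @param days Time points (default `c(0, 30, 60, 90)`); each needs an
#'   `f<day>` column in `regions`.
#' @param mean_reads,dispersion,gc_bias Passed to [simulate_profile()].
#' @param growth_baseline Baseline growth in drug at day 0 relative to
#'   untreated parental (default 0.04, i.e. 4%).
#' @param growth_sd Gaussian growth noise SD (default 0.015).
#' @param deterministic If `TRUE`, regions are assigned to the first
#'   `round(freq * n)` populations instead of Bernoulli draws, so
#'   realized frequencies match the trajectory exactly.
#' @param seed Optional integer seed (set once at entry).
#' @return A `cna_cohort_sim` list: `profiles` (long tibble of all
#'   sample profiles), `reference` (parental profile), `metadata`
#'   (sample_id, population_id, cell_line, day, growth columns), `truth`
#'   (population x day x region indicators with clone fractions),
#'   `regions`, `gc`, `layout`.
#' @export
simulate_cohort <- function(layout, regions = default_cohort_regions(layout),
                            n_populations = 20, days = c(0, 30, 60, 90),
                            mean_reads = 50, dispersion = 100,
                            gc_bias = c(1, 1.2, -5),
                            growth_baseline = 0.04, growth_sd = 0.015,
                            deterministic = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fcols <- paste0("f", days)
  miss <- setdiff(fcols, names(regions))
  if (length(miss) > 0) {
    stop("regions table lacks frequency columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- unlist(regions[fcols]) < 0 | unlist(regions[fcols]) > 1
  if (any(bad)) stop("frequencies must be in [0, 1].", call. = FALSE)
  gc <- simulate_gc(layout)
  ref <- simulate_profile(layout, simulate_karyotype(layout),
                          mean_reads = mean_reads,
                          dispersion = dispersion, gc = gc,
                          gc_bias = gc_bias, sample_id = "parental")
  truth <- list()
  profiles <- list()
  meta <- list()
  for (d in days) {
    ind <- draw_indicators(regions, paste0("f", d), n_populations,
                           deterministic)
    for (p in seq_len(n_populations)) {
      pid <- sprintf("pop%02d", p)
      sid <- sprintf("%s_d%02d", pid, d)
      on <- which(ind[p, ] == 1L)
      ev <- regions[on, c("chrom", "region", "delta",
                          "start_bp", "end_bp")]
      kar_base <- simulate_karyotype(layout)
      if (length(on) > 0) {
        fracs <- regions$clone_fraction[on]
        # compose fraction-weighted average over per-region subclones
        cn_avg <- kar_base$cn
        for (k in seq_along(on)) {
          one <- simulate_karyotype(layout, ev[k, ])
          cn_avg <- cn_avg + fracs[k] * (one$cn - kar_base$cn)
        }
        kar <- kar_base
        kar$cn <- cn_avg
      } else {
        kar <- kar_base
      }
      profiles[[sid]] <- simulate_profile(
        layout, kar, mean_reads = mean_reads, dispersion = dispersion,
        gc = gc, gc_bias = gc_bias, sample_id = sid)
      g_plus <- growth_baseline + sum(regions$beta[on]) +
        stats::rnorm(1, 0, growth_sd)
      g_minus <- stats::rnorm(1, 1, 0.1)
      meta[[sid]] <- tibble::tibble(
        sample_id = sid, population_id = pid, cell_line = "SIM",
        day = d, growth_plus_rev = max(g_plus, 0),
        growth_minus_rev = max(g_minus, 0.1))
      truth[[sid]] <- tibble::tibble(
        sample_id = sid, population_id = pid, day = d,
        region_id = regions$region_id,
        indicator = as.integer(ind[p, ]),
        clone_fraction = regions$clone_fraction)
    }
  }
  meta <- purrr::list_rbind(meta)
  meta$relative_growth <- meta$growth_plus_rev / meta$growth_minus_rev
  structure(
    list(profiles = purrr::list_rbind(profiles), reference = ref,
         metadata = meta, truth = purrr::list_rbind(truth),
         regions = regions, gc = gc, layout = layout),
    class = "cna_cohort_sim"
  )
}

# indicator matrix populations x regions honoring exclusivity groups
draw_indicators <- function(regions, fcol, n, deterministic) {
  m <- matrix(0L, nrow = n, ncol = nrow(regions))
  freqs <- regions[[fcol]]
  grp <- regions$group
  singles <- which(is.na(grp))
  for (j in singles) {
    if (deterministic) {
      k <- round(freqs[j] * n)
      if (k > 0) m[seq_len(k), j] <- 1L
    } else {
      m[, j] <- stats::rbinom(n, 1, freqs[j])
    }
  }
  for (g in unique(grp[!is.na(grp)])) {
    jj <- which(!is.na(grp) & grp == g)
    pj <- freqs[jj]
    if (sum(pj) > 1 + 1e-9) {
      stop("group ", g, " frequencies exceed 1.", call. = FALSE)
    }
    if (deterministic) {
      ks <- round(pj * n)
      pos <- 1L
      for (k in seq_along(jj)) {
        if (ks[k] > 0) {
          m[pos:(pos + ks[k] - 1L), jj[k]] <- 1L
          pos <- pos + ks[k]
        }
      }
    } else {
      pick <- apply(stats::rmultinom(n, 1, c(pj, 1 - sum(pj))), 2,
                    which.max)
      for (k in seq_along(jj)) m[pick == k, jj[k]] <- 1L
    }
  }
  m
}
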