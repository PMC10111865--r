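# Minimal hand-built calls/events for arithmetic checks.
fake_calls <- function(events, segments) {
  structure(list(events = events, segments = segments,
                 filter_log = tibble::tibble(),
                 flag_log = tibble::tibble(), params = list()),
            class = "cna_calls")
}

seg_row <- function(sample_id, chrom, n_bins, state) {
  tibble::tibble(sample_id = sample_id, chrom = chrom, arm = "q",
                 start_bin = 0, end_bin = n_bins, start_bp = 0,
                 end_bp = n_bins * 5e5, mean_cn_sample = 2,
                 mean_cn_ref = 2, n_bins = n_bins, delta = 0,
                 state = state, flagged = state == "i")
}

ev_row <- function(sample_id, chrom, arm, scope, direction, span_bins) {
  tibble::tibble(sample_id = sample_id, chrom = chrom, arm = arm,
                 scope = scope, direction = direction, start_bp = 0,
                 end_bp = span_bins * 5e5, span_bins = span_bins,
                 span_mb = span_bins / 2)
}

test_that("burden is the altered fraction of usable non-ignored bins", {
  segs <- dplyr::bind_rows(seg_row("s1", "c1", 90, "E"),
                           seg_row("s1", "c2", 10, "G"))
  calls <- fake_calls(ev_row("s1", "c2", "q", "arm", "gain", 10), segs)
  expect_equal(aneuploidy_burden(calls)$burden, 0.10)

  # euploid profile: zero burden
  calls0 <- fake_calls(ev_row("s1", "c", "q", "arm", "gain", 0)[0, ],
                       seg_row("s1", "c1", 100, "E"))
  expect_equal(aneuploidy_burden(calls0)$burden, 0)

  # focal events only count when asked
  callsf <- fake_calls(ev_row("s1", "c1", "q", "focal", "loss", 20),
                       seg_row("s1", "c1", 100, "E"))
  expect_equal(aneuploidy_burden(callsf)$burden, 0)
  expect_equal(aneuploidy_burden(callsf, include_focal = TRUE)$burden,
               0.2)

  # i segments leave numerator and denominator
  segsi <- dplyr::bind_rows(seg_row("s1", "c1", 50, "E"),
                            seg_row("s1", "c2", 50, "i"),
                            seg_row("s1", "c3", 50, "G"))
  callsi <- fake_calls(ev_row("s1", "c3", "q", "arm", "gain", 50), segsi)
  expect_equal(aneuploidy_burden(callsi)$burden, 0.5)

  # all-ignored profile is an error
  expect_error(aneuploidy_burden(
    fake_calls(ev_row("s1", "c", "q", "arm", "gain", 0)[0, ],
               seg_row("s1", "c1", 100, "i"))), "undefined")
})

test_that("frequency table counts populations, not events", {
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:20), population_id = paste0("p", 1:20),
    cell_line = "L", day = 90)
  # 4 of 20 populations carry a chrT4q loss (one with two events)
  ev <- dplyr::bind_rows(
    ev_row("s1", "chrT4", "q", "arm", "loss", 26),
    ev_row("s2", "chrT4", "q", "arm", "loss", 26),
    ev_row("s3", "chrT4", "q", "arm", "loss", 26),
    ev_row("s4", "chrT4", "q", "arm", "loss", 26),
    ev_row("s4", "chrT4", "q", "arm", "loss", 26)
  )
  freq <- frequency_table(ev, meta, toy)
  row <- freq[freq$chrom == "chrT4" & freq$arm == "q" &
                freq$direction == "loss", ]
  expect_equal(row$pct, 20)
  expect_equal(row$n_populations, 20)
  # all percentages bounded
  expect_true(all(freq$pct >= 0 & freq$pct <= 100))
})

test_that("whole-chromosome events count toward both arms", {
  meta <- tibble::tibble(sample_id = "s1", population_id = "p1",
                         cell_line = "L", day = 30)
  ev <- ev_row("s1", "chrT1", "", "whole_chromosome", "gain", 57)
  freq <- frequency_table(ev, meta, toy)
  gain_rows <- freq[freq$chrom == "chrT1" & freq$direction == "gain", ]
  expect_equal(sort(gain_rows$arm), c("p", "q"))
  expect_equal(gain_rows$pct, c(100, 100))
})

test_that("frequency table is invariant to population order", {
  meta <- tibble::tibble(
    sample_id = paste0("s", 1:6), population_id = paste0("p", 1:6),
    cell_line = "L", day = 90)
  ev <- dplyr::bind_rows(ev_row("s2", "chrT1", "q", "arm", "gain", 29),
                         ev_row("s5", "chrT1", "q", "arm", "gain", 29))
  a <- frequency_table(ev, meta, toy)
  b <- frequency_table(ev[2:1, ], meta[sample(6), ], toy)
  expect_equal(dplyr::arrange(a, chrom, arm, direction),
               dplyr::arrange(b, chrom, arm, direction))
})

test_that("CNA-type proportions sum to 100 and match planted counts", {
  meta <- tibble::tibble(sample_id = paste0("s", 1:10),
                         population_id = paste0("p", 1:10),
                         cell_line = "L", day = 30)
  ev <- dplyr::bind_rows(
    purrr::map(1:6, ~ev_row(paste0("s", .x), "c1", "",
                            "whole_chromosome", "gain", 57)),
    purrr::map(7:9, ~ev_row(paste0("s", .x), "c2", "p", "arm",
                            "loss", 20)),
    list(ev_row("s10", "c3", "q", "focal", "gain", 16)))
  prop <- cna_type_proportions(ev, meta)
  expect_equal(prop$pct[prop$scope == "whole_chromosome"], 60)
  expect_equal(prop$pct[prop$scope == "arm"], 30)
  expect_equal(prop$pct[prop$scope == "focal"], 10)
  expect_equal(sum(prop$pct), 100, tolerance = 1e-9)

  # a day with zero events warns and reports zeros
  meta2 <- dplyr::bind_rows(meta, tibble::tibble(
    sample_id = "s11", population_id = "p11", cell_line = "L",
    day = 60))
  expect_warning(prop2 <- cna_type_proportions(ev, meta2), "zero events")
  expect_equal(prop2$pct[prop2$day == 60], c(0, 0, 0))
})

test_that("F-test matches the closed form and the squared-t identity", {
  x <- c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1)
  y <- c(1.1, 0.9, 1.0, 1.2, 2.1, 1.8, 2.2, 2.0, 1.9, 2.3)
  ft <- association_ftest(x, y)
  # closed-form OLS on paper
  b <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - b * mean(x)
  expect_equal(ft$slope, b, tolerance = 1e-12)
  expect_equal(ft$intercept, a, tolerance = 1e-12)
  res <- y - a - b * x
  sse <- sum(res^2)
  ssr <- sum((a + b * x - mean(y))^2)
  f_manual <- (ssr / 1) / (sse / (length(x) - 2))
  expect_equal(ft$statistic, f_manual, tolerance = 1e-10)
  expect_equal(ft$p_value,
               stats::pf(f_manual, 1, 8, lower.tail = FALSE),
               tolerance = 1e-12)
  # identity with the squared t statistic of the slope
  tt <- summary(stats::lm(y ~ x))$coefficients["x", "t value"]
  expect_equal(ft$statistic, tt^2, tolerance = 1e-10)
  # perfect-fit limit
  pf_fit <- association_ftest(x, 2 * x + 1)
  expect_true(pf_fit$perfect_fit)
  expect_equal(pf_fit$p_value, 0)
  # degenerate x
  expect_error(association_ftest(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("tidy/glance methods expose the fit in broom shape", {
  ft <- association_ftest(1:10, 2 * (1:10) + rnorm(10))
  td <- tidy(ft)
  expect_equal(td$term, c("(Intercept)", "x"))
  gl <- glance(ft)
  expect_named(gl, c("r.squared", "statistic", "p.value", "nobs",
                     "perfect.fit"))
  expect_equal(gl$nobs, 10)
})

test_that("mutual exclusivity is detected; degenerate pairs are skipped", {
  ind <- tibble::tibble(
    population_id = paste0("p", 1:20),
    a = rep(c(1, 0), each = 10),
    b = rep(c(0, 1), each = 10),
    flat = 0)
  scan <- anticorrelation_scan(ind, tibble::tibble(a = "a", b = "b"))
  expect_lt(scan$slope, 0)
  expect_equal(scan$n01 + scan$n10, 20)
  expect_equal(scan$n11, 0)
  expect_true(scan$p_value < 1e-6)

  scan2 <- anticorrelation_scan(ind, tibble::tibble(a = "a",
                                                    b = "flat"))
  expect_true(scan2$skipped)
  expect_match(scan2$reason, "degenerate")
})

test_that("independent indicators give uniform-ish p-values", {
  set.seed(31)
  ps <- replicate(300, {
    ind <- tibble::tibble(population_id = 1:20,
                          a = stats::rbinom(20, 1, 0.5),
                          b = stats::rbinom(20, 1, 0.5))
    s <- anticorrelation_scan(ind, tibble::tibble(a = "a", b = "b"))
    if (s$skipped) NA else s$p_value
  })
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 250)
  # null p-values: roughly uniform (binary x gives discrete p, so loose)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.12)
  expect_lt(mean(ps < 0.05), 0.1)
})

test_that("planted exclusivity with noise is detected with high power", {
  set.seed(32)
  hits <- 0
  for (r in 1:100) {
    base <- stats::rbinom(20, 1, 0.5)
    a <- base
    b <- 1 - base
    flip <- stats::runif(20) < 0.1   # 10% noise
    b[flip] <- 1 - b[flip]
    ind <- tibble::tibble(population_id = 1:20, a = a, b = b)
    s <- anticorrelation_scan(ind, tibble::tibble(a = "a", b = "b"))
    if (!s$skipped && s$p_value < 0.05 && s$slope < 0) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("cancer-frequency correlation recovers identity and planted signal", {
  arms <- paste0("arm", 1:12)
  adapted <- tibble::tibble(
    cell_line = "L", day = 90,
    chrom = arms, arm = "", direction = "gain",
    n_populations = 20, n_with_event = 0,
    pct = c(80, 60, 50, 40, 10, 5, 5, 0, 0, 20, 30, 15))
  cancer <- tibble::tibble(arm = arms,
                           gain_freq = adapted$pct / 100,
                           loss_freq = 0)
  res <- cancer_frequency_correlation(adapted, cancer, "gain")
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$n_arms, 12)

  # permuted labels: correlation collapses
  set.seed(33)
  rs <- replicate(200, {
    cancer_perm <- cancer
    cancer_perm$gain_freq <- sample(cancer_perm$gain_freq)
    cancer_frequency_correlation(adapted, cancer_perm, "gain")$r
  })
  expect_lt(abs(mean(rs)), 0.15)

  # unmatched arms are an error that names the arm
  expect_error(
    cancer_frequency_correlation(adapted, cancer[-1, ], "gain"),
    "arm1")
})

test_that("indicator matrix maps arm and whole-chromosome events", {
  meta <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                         population_id = c("p1", "p2", "p3"),
                         cell_line = "L", day = 90)
  ev <- dplyr::bind_rows(
    ev_row("s1", "chrT1", "q", "arm", "gain", 29),
    ev_row("s2", "chrT1", "", "whole_chromosome", "gain", 57),
    ev_row("s3", "chrT2", "p", "arm", "loss", 20))
  ind <- event_indicator_matrix(ev, meta, day = 90,
                                regions = c("chrT1q_gain",
                                            "chrT2p_loss"))
  expect_equal(ind$chrT1q_gain, c(1, 1, 0))  # whole counts for the arm
  expect_equal(ind$chrT2p_loss, c(0, 0, 1))
})
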