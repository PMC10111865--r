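test_that("breakpoint union re-cuts both profiles one-to-one", {
  set.seed(21)
  # noiseless profiles with distinct structures per profile
  cn_s <- rep(2, nrow(toy_grid))
  cn_r <- rep(2, nrow(toy_grid))
  q1 <- which(toy_grid$chrom == "chrT1" & toy_grid$usable)
  cn_s[q1[31:57]] <- 3                      # sample cp at usable idx 30
  prof_s <- profile_from_cn(cn_s, toy)
  prof_r <- profile_from_cn(cn_r, toy, sample_id = "wt")
  seg_s <- segment_profile(prof_s, toy, sigma2 = 0.01)
  seg_r <- segment_profile(prof_r, toy, sigma2 = 0.01)

  al <- harmonize_breakpoints(seg_s, seg_r, prof_s, prof_r, toy)
  a1 <- al[al$chrom == "chrT1", ]
  # the sample's breakpoints (plus centromere split) cut the flat
  # reference into aligned segments with recomputed means
  expect_gte(nrow(a1), 3)
  expect_true(all(abs(a1$mean_cn_ref - 2) < 1e-9))
  expect_identical(a1$start_bin[-1], a1$end_bin[-nrow(a1)])

  # identical inputs are a fixed point
  al2 <- harmonize_breakpoints(seg_s, seg_s, prof_s, prof_s, toy)
  expect_equal(al2$start_bin, seg_s$start_bin)
  expect_equal(al2$end_bin, seg_s$end_bin)
})

test_that("breakpoint union matches the set-union oracle", {
  # hand-built segment tables on one 60-bin chromosome
  mk_segs <- function(cuts, n = 57) {   # chrT1 has 57 usable bins
    bounds <- c(0L, cuts, n)
    tibble::tibble(
      sample_id = "s", chrom = "chrT1", arm = "q",
      start_bin = bounds[-length(bounds)], end_bin = bounds[-1],
      start_bp = 0, end_bp = 0, n_bins = diff(bounds), mean_cn = 2)
  }
  prof <- profile_from_cn(rep(2, nrow(toy_grid)), toy)
  al <- harmonize_breakpoints(mk_segs(c(10L, 40L)), mk_segs(25L),
                              prof, prof, toy)
  a1 <- al[al$chrom == "chrT1", ]
  expect_equal(sort(a1$end_bin), sort(unique(c(10, 25, 40, 57))))
  expect_equal(nrow(a1), 4)
})

test_that("state thresholds are strict and the 15-bin rule filters", {
  aligned <- dplyr::bind_rows(
    aligned_row(0, 20, +1.0),    # clear gain over 20 bins
    aligned_row(20, 40, +0.4),   # below threshold
    aligned_row(40, 60, +0.5),   # exactly +0.5: strict, so E
    aligned_row(60, 74, -0.8),   # loss but only 14 bins
    aligned_row(74, 90, -0.8),   # loss with 16 bins
    aligned_row(90, 110, -0.5)   # exactly -0.5: strict, so E
  )
  called <- call_states(aligned)
  expect_equal(called$state, c("G", "E", "E", "E", "L", "E"))
  expect_equal(called$state_raw, c("G", "E", "E", "L", "L", "E"))
  expect_equal(which(called$length_filtered), 4)
})

test_that("flags override states and propagate by any overlap", {
  aligned <- dplyr::bind_rows(
    aligned_row(0, 20, +1.0),
    aligned_row(20, 40, 0),
    aligned_row(40, 60, -1.0)
  )
  called <- call_states(aligned)
  flags <- tibble::tibble(chrom = "mini1", start_bp = 19.5e6,
                          end_bp = 45e6, label = "inherent")
  flagged <- propagate_flags(called, flags)
  # segment 1 straddles the flag start by half a bin: any-overlap -> i
  expect_equal(flagged$state, c("i", "i", "i"))
  expect_equal(flagged$flagged, c(TRUE, TRUE, TRUE))

  # empty flag set leaves everything unchanged
  same <- propagate_flags(called, NULL)
  expect_equal(same$state, called$state)
  disjoint <- propagate_flags(called, tibble::tibble(
    chrom = "other", start_bp = 0, end_bp = 1e9))
  expect_equal(disjoint$state, called$state)
})

test_that("merging removes adjacent same-state runs and conserves bins", {
  set.seed(22)
  for (r in 1:100) {
    n_seg <- sample(2:12, 1)
    cuts <- sort(sample(1:119, n_seg - 1))
    bounds <- c(0L, cuts, 120L)
    states <- sample(c("E", "G", "L", "i"), n_seg, replace = TRUE)
    segs <- purrr::map2(bounds[-length(bounds)], bounds[-1],
                        function(a, b) aligned_row(a, b, 0)) |>
      purrr::list_rbind()
    segs$state <- states
    segs$mean_cn_sample <- stats::runif(n_seg, 1, 3)
    merged <- merge_same_state(segs)
    expect_true(all(merged$state[-1] != merged$state[-nrow(merged)]))
    expect_equal(sum(merged$n_bins), 120L)
    # bin-weighted means are conserved in aggregate
    expect_equal(sum(merged$mean_cn_sample * merged$n_bins),
                 sum(segs$mean_cn_sample * segs$n_bins),
                 tolerance = 1e-9)
  }
})

test_that("merging can cross the centromere only on matching states", {
  segs <- dplyr::bind_rows(
    aligned_row(0, 4, 0, arm = "p"),
    aligned_row(4, 8, 0, arm = "q")
  )
  segs$state <- c("E", "E")
  merged <- merge_same_state(segs)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$arm, "pq")

  segs$state <- c("G", "E")
  merged <- merge_same_state(segs)
  expect_equal(nrow(merged), 2)
})

test_that("events classify as whole chromosome, arm, or focal", {
  grid <- build_bin_grid(mini_layout)
  u <- usable <- grid$usable
  mk_states <- function(chrom, cuts, states) {
    gch <- grid[grid$chrom == chrom & grid$usable, ]
    bounds <- c(0L, cuts, nrow(gch))
    purrr::map(seq_len(length(bounds) - 1), function(i) {
      idx <- (bounds[i] + 1):bounds[i + 1]
      arms <- unique(gch$arm[idx])
      tibble::tibble(
        sample_id = "s", chrom = chrom,
        arm = if (length(arms) == 1) arms else "pq",
        start_bin = bounds[i], end_bin = bounds[i + 1],
        start_bp = gch$start[idx[1]], end_bp = gch$end[idx[length(idx)]],
        n_bins = length(idx), mean_cn_sample = 2, mean_cn_ref = 2,
        delta = 0, state = states[i], flagged = FALSE)
    }) |> purrr::list_rbind()
  }

  # whole-chromosome gain: every usable bin G
  ev <- classify_events(mk_states("mini1", integer(0), "G"), mini_layout)
  expect_equal(ev$scope, "whole_chromosome")
  expect_equal(ev$direction, "gain")
  expect_equal(ev$span_bins,
               sum(grid$usable & grid$chrom == "mini1"))

  # full p-arm loss, q equal -> arm loss
  ev <- classify_events(mk_states("mini1", 4L, c("L", "E")), mini_layout)
  expect_equal(ev$scope, "arm")
  expect_equal(ev$arm, "p")
  expect_equal(ev$direction, "loss")

  # interior loss inside q -> focal
  ev <- classify_events(mk_states("mini1", c(4L, 5L, 7L),
                                  c("E", "E", "L", "E")), mini_layout)
  expect_equal(ev$scope, "focal")
  expect_equal(ev$span_bins, 2)

  # acrocentric full-q change: arm by default, whole under the flag
  ev <- classify_events(mk_states("mini2", integer(0), "G"), mini_layout)
  expect_equal(ev$scope, "arm")
  ev <- classify_events(mk_states("mini2", integer(0), "G"), mini_layout,
                        acrocentric_as_whole = TRUE)
  expect_equal(ev$scope, "whole_chromosome")
})

test_that("negating deltas swaps G and L and fixes E/i (sign symmetry)", {
  set.seed(23)
  aligned <- purrr::map(0:9, function(i) {
    aligned_row(i * 20, (i + 1) * 20, stats::runif(1, -1.5, 1.5))
  }) |> purrr::list_rbind()
  a <- call_states(aligned)
  flipped <- aligned
  flipped$mean_cn_sample <- 2 * flipped$mean_cn_ref -
    flipped$mean_cn_sample
  b <- call_states(flipped)
  swap <- c(G = "L", L = "G", E = "E", i = "i")
  expect_equal(unname(swap[a$state]), b$state)
})

test_that("end-to-end calling is deterministic", {
  pair <- withr::with_seed(24, simulate_pair(
    tibble::tibble(chrom = "chrT2", region = "p", delta = -1L)))
  a <- call_cna(pair$sample, pair$reference, toy)
  b <- call_cna(pair$sample, pair$reference, toy)
  expect_identical(a$segments, b$segments)
  expect_identical(a$events, b$events)
})

test_that("clonal arm events are called; 20% subclonal events stay E", {
  set.seed(25)
  gc <- simulate_gc(toy)
  kar0 <- simulate_karyotype(toy)
  karG <- simulate_karyotype(toy, tibble::tibble(
    chrom = "chrT2", region = "q", delta = 1L))
  n_called_sub <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    ref <- preprocess_profile(
      simulate_profile(toy, kar0, gc = gc, sample_id = "wt"), toy)
    # subclonal at fraction 0.2: population-average delta 0.2
    smp <- preprocess_profile(
      simulate_profile(toy, list(kar0, karG), fractions = c(0.8, 0.2),
                       gc = gc, sample_id = "s"), toy)
    ev <- call_cna(smp, ref, toy)$events
    if (any(ev$chrom == "chrT2" & ev$direction == "gain")) {
      n_called_sub <- n_called_sub + 1
    }
  }
  expect_lte(n_called_sub / reps, 0.05)
})
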