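#' Harmonize breakpoints between a sample and its parental reference
#'
#' State calling is differential, so sample and wild-type segmentations
#' are re-cut on the union of their breakpoint sets per chromosome; the
#' resulting one-to-one aligned segments have identical coordinates and
#' per-segment means recomputed on each profile's own copy numbers. If a
#' change point exists in only one of the two profiles, it is introduced
#' into the other (this is the step that can over-segment; see
#' [merge_same_state()]).
#'
#' @param sample_segments,ref_segments Segment tibbles from
#'   [segment_profile()] for the sample and the matched wild type.
#' @param sample_profile,ref_profile The corresponding normalized
#'   profiles (with `cn`).
#' @param layout A `genome_layout`.
#' @return Aligned segment tibble: `sample_id, chrom, arm, start_bin,
#'   end_bin, start_bp, end_bp, n_bins, mean_cn_sample, mean_cn_ref`.
#' @export
harmonize_breakpoints <- function(sample_segments, ref_segments,
                                  sample_profile, ref_profile, layout) {
  ub_s <- usable_bins(sample_profile, layout)
  ub_r <- usable_bins(ref_profile, layout)
  if (!identical(ub_s[c("chrom", "start", "end")],
                 ub_r[c("chrom", "start", "end")])) {
    stop("sample and reference profiles are on different grids.",
         call. = FALSE)
  }
  sid <- if ("sample_id" %in% names(sample_profile)) {
    sample_profile$sample_id[1]
  } else "sample"
  purrr::map(unique(ub_s$chrom), function(ch) {
    u <- ub_s[ub_s$chrom == ch, ]
    if (nrow(u) == 0) return(empty_aligned())
    bp_s <- inner_boundaries(sample_segments, ch)
    bp_r <- inner_boundaries(ref_segments, ch)
    cps <- sort(union(bp_s, bp_r))
    segs <- cut_segments(u, cps, sid)
    ref_cn <- ub_r$cn[ub_r$chrom == ch]
    segs$mean_cn_sample <- segs$mean_cn
    segs$mean_cn_ref <- vapply(seq_len(nrow(segs)), function(i) {
      mean(ref_cn[(segs$start_bin[i] + 1):segs$end_bin[i]])
    }, numeric(1))
    segs$mean_cn <- NULL
    segs
  }) |> purrr::list_rbind()
}

empty_aligned <- function() {
  out <- empty_segments()
  out$mean_cn <- NULL
  out$mean_cn_sample <- double()
  out$mean_cn_ref <- double()
  out
}

inner_boundaries <- function(segments, chrom) {
  s <- segments[segments$chrom == chrom, ]
  if (nrow(s) < 2) return(integer(0))
  sort(unique(s$end_bin[-nrow(s)]))
}

#' Call gain/loss states on aligned segments
#'
#' For each aligned segment the copy-number difference
#' `delta = mean_cn_sample - mean_cn_ref` is thresholded with strict
#' inequalities: `delta > gain_threshold` is a gain (G),
#' `delta < loss_threshold` a loss (L), anything else equal (E) — a
#' delta of exactly +0.5 is E. Gains/losses shorter than `min_bins`
#' bins (15 bins = 7.5 Mb at 500-kb bins) are relabeled E so they are
#' not counted; relabeled rows are marked in the `length_filtered`
#' column (the filter log).
#'
#' @param aligned Output of [harmonize_breakpoints()].
#' @param gain_threshold Gain threshold in copies (default +0.5).
#' @param loss_threshold Loss threshold in copies (default -0.5).
#' @param min_bins Minimum countable segment length in bins (default 15).
#' @return `aligned` with columns `delta`, `state_raw` (pre-filter),
#'   `state`, `length_filtered`.
#' @export
call_states <- function(aligned, gain_threshold = 0.5,
                        loss_threshold = -0.5, min_bins = 15L) {
  out <- aligned
  out$delta <- out$mean_cn_sample - out$mean_cn_ref
  out$state_raw <- dplyr::case_when(
    out$delta > gain_threshold ~ "G",
    out$delta < loss_threshold ~ "L",
    TRUE ~ "E"
  )
  out$length_filtered <- out$state_raw %in% c("G", "L") &
    out$n_bins < min_bins
  out$state <- ifelse(out$length_filtered, "E", out$state_raw)
  out
}

#' Propagate wild-type flags onto sample segments
#'
#' Segments overlapping a flagged region (a pre-existing parental CNA
#' listed in a flag table) by at least one bin are set to state "i"
#' (ignore), which overrides G/L/E; flagged rows are marked in the
#' `flagged` column (the flag log).
#'
#' @param states State-labeled segments from [call_states()].
#' @param flags Tibble `chrom, start_bp, end_bp` (+ optional `label`),
#'   e.g. from [read_flags()]; `NULL` or empty leaves states unchanged.
#' @return `states` with columns `flagged` and updated `state`.
#' @export
propagate_flags <- function(states, flags = NULL) {
  out <- states
  out$flagged <- FALSE
  if (is.null(flags) || nrow(flags) == 0) return(out)
  for (i in seq_len(nrow(flags))) {
    hit <- out$chrom == flags$chrom[i] &
      out$start_bp < flags$end_bp[i] &
      out$end_bp > flags$start_bp[i]
    out$flagged <- out$flagged | hit
  }
  out$state <- ifelse(out$flagged, "i", out$state)
  out
}

#' Merge adjacent same-state segments
#'
#' Breakpoint harmonization and the centromere-split heuristic
#' over-segment the profiles; maximal runs of adjacent segments with the
#' same state within a chromosome are merged back (bin-weighted means).
#' Merging crosses the centromere exactly when the flanking segments on
#' both arms share the state, restoring the single-segment
#' representation of an unchanged or whole-chromosome-changed
#' chromosome.
#'
#' @param states State-labeled segments ([call_states()] /
#'   [propagate_flags()] output), in genomic order.
#' @return Merged segment tibble with no two adjacent segments of equal
#'   state within a chromosome; columns as input minus the pre-filter
#'   audit columns, plus `state`.
#' @export
merge_same_state <- function(states) {
  if (!"flagged" %in% names(states)) states$flagged <- FALSE
  states |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::arrange(.data$start_bin, .by_group = TRUE) |>
    dplyr::mutate(run = rl_run_id(.data$state)) |>
    dplyr::group_by(.data$sample_id, .data$chrom, .data$run) |>
    dplyr::summarise(
      arm = if (dplyr::n_distinct(.data$arm) == 1) .data$arm[1] else "pq",
      start_bin = min(.data$start_bin),
      end_bin = max(.data$end_bin),
      start_bp = min(.data$start_bp),
      end_bp = max(.data$end_bp),
      mean_cn_sample = stats::weighted.mean(.data$mean_cn_sample,
                                            .data$n_bins),
      mean_cn_ref = stats::weighted.mean(.data$mean_cn_ref,
                                         .data$n_bins),
      n_bins = sum(.data$n_bins),
      delta = .data$mean_cn_sample - .data$mean_cn_ref,
      state = .data$state[1],
      flagged = any(.data$flagged),
      .groups = "drop"
    ) |>
    dplyr::select(-"run") |>
    dplyr::arrange(.data$sample_id, .data$chrom, .data$start_bin)
}

# run id over consecutive equal states
rl_run_id <- function(state) {
  cumsum(c(TRUE, state[-1] != state[-length(state)]))
}

#' Classify merged segments into CNA events
#'
#' A chromosome whose usable bins all share one changed direction is a
#' whole-chromosome event; an arm fully changed in one direction (with
#' the chromosome not fully changed) is an arm event; any maximal
#' changed run covering a strict subset of an arm is a focal event.
#' Flagged ("i") bins are excluded from consideration: an arm counts as
#' fully changed when all of its non-ignored usable bins share the
#' direction. For acrocentric chromosomes only the q arm exists in the
#' data; a fully changed q arm is reported as an arm event by default,
#' or as a whole-chromosome event when `acrocentric_as_whole = TRUE`.
#'
#' @param segmented Merged segments from [merge_same_state()].
#' @param layout A `genome_layout`.
#' @param acrocentric_as_whole Count a fully changed acrocentric q arm
#'   as a whole-chromosome event (default `FALSE`).
#' @return Event tibble: `sample_id, chrom, arm` ("" for
#'   whole-chromosome events), `scope` (`whole_chromosome`/`arm`/
#'   `focal`), `direction` (`gain`/`loss`), `start_bp, end_bp,
#'   span_bins, span_mb`.
#' @export
classify_events <- function(segmented, layout,
                            acrocentric_as_whole = FALSE) {
  grid <- usable_index(build_bin_grid(layout))
  bs <- bin_size(layout)
  acro <- stats::setNames(layout$acrocentric, layout$chrom)
  purrr::map(
    unique(segmented$sample_id),
    function(sid) {
      segs <- segmented[segmented$sample_id == sid, ]
      purrr::map(unique(segs$chrom), function(ch) {
        classify_chrom(segs[segs$chrom == ch, ], ch, sid,
                       grid[grid$chrom == ch & grid$usable, ],
                       acro[[ch]], acrocentric_as_whole, bs)
      }) |> purrr::list_rbind()
    }
  ) |> purrr::list_rbind()
}

classify_chrom <- function(segs, ch, sid, gch, is_acro,
                           acro_as_whole, bs) {
  n <- nrow(gch)
  if (n == 0 || nrow(segs) == 0) return(empty_events())
  # per-usable-bin state vector
  st <- rep(NA_character_, n)
  for (i in seq_len(nrow(segs))) {
    st[(segs$start_bin[i] + 1):segs$end_bin[i]] <- segs$state[i]
  }
  arms <- gch$arm
  out <- list()
  for (dir_state in c("G", "L")) {
    direction <- if (dir_state == "G") "gain" else "loss"
    consider <- st != "i"
    present_arms <- unique(arms)
    # fully changed = every arm has observable bins and all of them agree
    whole <- any(consider) && all(st[consider] == dir_state) &&
      all(vapply(present_arms,
                 function(a) any(consider & arms == a), logical(1)))
    if (whole && (!is_acro || acro_as_whole) &&
        (length(present_arms) == 2 || is_acro)) {
      idx <- which(consider)
      out[[length(out) + 1]] <- event_row(
        sid, ch, "", "whole_chromosome", direction, gch, idx, bs)
      next
    }
    for (a in present_arms) {
      ai <- which(arms == a & consider)
      if (length(ai) == 0) next
      if (all(st[ai] == dir_state)) {
        out[[length(out) + 1]] <- event_row(
          sid, ch, a, "arm", direction, gch, ai, bs)
      } else {
        runs <- changed_runs(st, ai, dir_state)
        for (r in runs) {
          out[[length(out) + 1]] <- event_row(
            sid, ch, a, "focal", direction, gch, r, bs)
        }
      }
    }
  }
  if (length(out) == 0) return(empty_events())
  purrr::list_rbind(out)
}

# maximal runs of bins in state `dir` within the arm index set ai
changed_runs <- function(st, ai, dir) {
  hit <- st[ai] == dir
  if (!any(hit)) return(list())
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  purrr::map2(starts[r$values], ends[r$values],
              function(s, e) ai[s:e])
}

event_row <- function(sid, ch, arm, scope, direction, gch, idx, bs) {
  tibble::tibble(
    sample_id = sid, chrom = ch, arm = arm, scope = scope,
    direction = direction,
    start_bp = min(gch$start[idx]), end_bp = max(gch$end[idx]),
    span_bins = length(idx), span_mb = length(idx) * bs / 1e6
  )
}

empty_events <- function() {
  tibble::tibble(sample_id = character(), chrom = character(),
                 arm = character(), scope = character(),
                 direction = character(), start_bp = double(),
                 end_bp = double(), span_bins = integer(),
                 span_mb = double())
}

#' Full differential CNA calling for one sample
#'
#' Runs the whole calling chain: segmentation of sample and matched
#' wild-type profiles ([segment_profile()]), breakpoint harmonization,
#' strict-threshold state calling with the minimum-length rule, flag
#' propagation, oversegmentation merge, and event classification.
#'
#' @param sample_profile,ref_profile Normalized single-sample profiles
#'   (with `cn`).
#' @param layout A `genome_layout`.
#' @param penalty,min_seg,sigma2 Segmentation parameters ([pelt()]).
#' @param gain_threshold,loss_threshold,min_bins Calling parameters
#'   ([call_states()]).
#' @param flags Optional flagged-region table ([propagate_flags()]).
#' @param acrocentric_as_whole See [classify_events()].
#' @return A `cna_calls` object: list with `segments` (merged, state
#'   labeled), `events`, `filter_log` (length-relabeled segments),
#'   `flag_log` (flag-overridden segments), and the parameters used.
#'   `tidy()` returns the segment table, `glance()` a one-row summary.
#' @examples
#' layout <- toy_genome()
#' set.seed(1)
#' gc <- simulate_gc(layout)
#' ref <- simulate_profile(layout, simulate_karyotype(layout), gc = gc,
#'                         sample_id = "wt")
#' kar <- simulate_karyotype(layout,
#'   events = tibble::tibble(chrom = "chrT2", region = "q", delta = 1))
#' smp <- simulate_profile(layout, kar, gc = gc, sample_id = "s1")
#' prep <- function(p) normalize_to_copy_number(correct_gc(p, layout), layout)
#' calls <- call_cna(prep(smp), prep(ref), layout)
#' calls$events
#' @export
call_cna <- function(sample_profile, ref_profile, layout,
                     penalty = NULL, min_seg = 2L, sigma2 = NULL,
                     gain_threshold = 0.5, loss_threshold = -0.5,
                     min_bins = 15L, flags = NULL,
                     acrocentric_as_whole = FALSE) {
  seg_s <- segment_profile(sample_profile, layout, penalty = penalty,
                           min_seg = min_seg, sigma2 = sigma2)
  seg_r <- segment_profile(ref_profile, layout, penalty = penalty,
                           min_seg = min_seg, sigma2 = sigma2)
  aligned <- harmonize_breakpoints(seg_s, seg_r, sample_profile,
                                   ref_profile, layout)
  called <- call_states(aligned, gain_threshold = gain_threshold,
                        loss_threshold = loss_threshold,
                        min_bins = min_bins)
  called <- propagate_flags(called, flags)
  # Merge on the pre-filter state so that a changed run split by copied
  # wild-type breakpoints re-joins before the minimum-length rule is
  # applied; the rule is then re-applied on merged lengths. Both the
  # sub-segment and the merged-stage relabelings are logged.
  pre <- called
  pre$state <- ifelse(pre$flagged, "i", pre$state_raw)
  merged <- merge_same_state(pre)
  short <- merged$state %in% c("G", "L") & merged$n_bins < min_bins
  post_log <- merged[short, ]
  merged$state[short] <- "E"
  merged <- merge_same_state(merged)
  events <- classify_events(merged, layout,
                            acrocentric_as_whole = acrocentric_as_whole)
  log_cols <- c("sample_id", "chrom", "arm", "start_bp", "end_bp",
                "n_bins", "delta")
  filter_log <- dplyr::bind_rows(
    dplyr::mutate(called[called$length_filtered, log_cols],
                  stage = "subsegment"),
    dplyr::mutate(post_log[, log_cols], stage = "merged"))
  structure(
    list(
      segments = merged,
      events = events,
      filter_log = filter_log,
      flag_log = called[called$flagged, ],
      params = list(penalty = penalty, min_seg = min_seg,
                    gain_threshold = gain_threshold,
                    loss_threshold = loss_threshold, min_bins = min_bins,
                    acrocentric_as_whole = acrocentric_as_whole)
    ),
    class = "cna_calls"
  )
}

#' @export
print.cna_calls <- function(x, ...) {
  cat("CNA calls:", nrow(x$events), "event(s) over",
      nrow(x$segments), "merged segment(s)\n")
  if (nrow(x$events) > 0) print(x$events, ...)
  invisible(x)
}
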