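# Shared desk-scale fixtures, all generated in code.

toy <- toy_genome()
toy_grid <- build_bin_grid(toy)

# A tiny two-chromosome layout for hand-checkable cases:
# mini1: 10 bins, centromere masks bins 4-5 (p = 0-3, q = 6-9)
# mini2: 8 bins, acrocentric, centromere masks bin 1 (q usable = 2-7)
mini_layout <- genome_layout(tibble::tibble(
  chrom = c("mini1", "mini2"),
  length = c(10e6, 8e6),
  cen_start = c(4.2e6, 1.2e6),
  cen_end = c(5.8e6, 1.8e6),
  acrocentric = c(FALSE, TRUE),
  baseline_cn = c(2L, 2L)
), bin_size = 1e6)

# Build a profile directly from a per-bin cn vector (no noise), with
# flat counts/gc so IO and calling stages can run on exact values.
profile_from_cn <- function(cn, layout, sample_id = "s") {
  grid <- build_bin_grid(layout)
  stopifnot(length(cn) == nrow(grid))
  tibble::tibble(
    sample_id = sample_id, chrom = grid$chrom, start = grid$start,
    end = grid$end, count = 100L, gc = 0.45, cn = as.numeric(cn)
  )
}

# Noiseless segment tables for state-calling tests: one row per segment
# on a single synthetic chromosome of `n` usable bins.
aligned_row <- function(start_bin, end_bin, delta, arm = "q",
                        chrom = "mini1", ref = 2) {
  tibble::tibble(
    sample_id = "s", chrom = chrom, arm = arm,
    start_bin = start_bin, end_bin = end_bin,
    start_bp = start_bin * 1e6, end_bp = end_bin * 1e6,
    n_bins = end_bin - start_bin,
    mean_cn_sample = ref + delta, mean_cn_ref = ref
  )
}

# Simulated sample/reference pair on the toy genome with given events.
simulate_pair <- function(events = NULL, gc = NULL, mean_reads = 50,
                          layout = toy) {
  if (is.null(gc)) gc <- simulate_gc(layout)
  ref <- simulate_profile(layout, simulate_karyotype(layout), gc = gc,
                          mean_reads = mean_reads, sample_id = "wt")
  kar <- simulate_karyotype(layout, events)
  smp <- simulate_profile(layout, kar, gc = gc,
                          mean_reads = mean_reads, sample_id = "s1")
  list(sample = preprocess_profile(smp, layout),
       reference = preprocess_profile(ref, layout),
       gc = gc)
}
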