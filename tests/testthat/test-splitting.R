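# Threshold- and length-splitting.

test_that("split configuration derives the length cap from the bit width", {
  cfg <- split_config(length_bits = 9L)
  expect_equal(cfg$l_max, 511L)
  expect_true(cfg$do_threshold_split)
  expect_equal(split_config(11L)$l_max, 2047L)
  expect_error(split_config(0L))
})

test_that("length-splitting follows the all-but-last-at-cap rule", {
  rows <- data.frame(c = 1L, h = 1L, l = 10L)
  out <- split_by_length(rows, 4L)
  expect_equal(out$l, c(4L, 4L, 2L))
  expect_equal(out$h, c(1L, 5L, 9L))

  # exact multiples yield no zero-length remainder row
  out8 <- split_by_length(data.frame(c = 2L, h = 1L, l = 8L), 4L)
  expect_equal(out8$l, c(4L, 4L))

  # below the cap: unchanged
  out3 <- split_by_length(data.frame(c = 3L, h = 1L, l = 3L), 4L)
  expect_equal(out3$l, 3L)

  # mixed row set keeps the partition
  rows <- data.frame(c = c(1L, 2L, 3L), h = c(1L, 13L, 14L), l = c(12L, 1L, 9L))
  out <- split_by_length(rows, 5L)
  expect_equal(out$l, c(5L, 5L, 2L, 1L, 5L, 4L))
  expect_equal(out$h, cumsum(c(1L, out$l[-length(out$l)])))
})

test_that("threshold-splitting makes every threshold trivial within 2r rows", {
  for (seed in 1:15) {
    n <- sample(50:1500, 1)
    tx <- text_from_string(random_dna(seed + 60, n))
    b <- build_suffix_bundle(tx)
    rl <- run_length_encode(b)
    ts <- compute_thresholds(b, rl)
    out <- split_at_thresholds(rl$runs, ts)
    expect_lte(nrow(out), rl$r + ts$n_pairs)
    expect_lte(nrow(out), 2L * rl$r)
    expect_equal(sum(out$l), b$n)
    thr <- map_thresholds_to_rows(ts, out)
    for (y in 1:4) {
      v <- thr[, y]
      ok <- is.na(v) | v == 0L | v == out$l
      expect_true(all(ok))
    }
  }
})

test_that("cutting a row at an interior threshold yields up/down trivial sub-rows", {
  # the spec-level semantics on a concrete case with an interior threshold
  fx <- adversarial_fixtures()
  tx <- text_from_string(fx$nontrivial_threshold)
  b <- build_suffix_bundle(tx)
  rl <- run_length_encode(b)
  ts <- compute_thresholds(b, rl)
  before <- map_thresholds_to_rows(ts, rl$runs)
  interior <- which(before > 0L & before < rl$runs$l, arr.ind = TRUE)
  expect_gte(nrow(interior), 1L)
  out <- split_at_thresholds(rl$runs, ts)
  expect_gt(nrow(out), rl$r)
  after <- map_thresholds_to_rows(ts, out)
  # each formerly-interior threshold now sits at l of one sub-row and 0 of the next
  for (k in seq_len(nrow(interior))) {
    q <- interior[k, 1L]
    y <- interior[k, 2L]
    t_global <- rl$runs$h[q] + before[q, y]
    qs <- which(out$h >= rl$runs$h[q] & out$h < rl$runs$h[q] + rl$runs$l[q])
    cutrow <- qs[out$h[qs] + out$l[qs] == t_global]
    expect_equal(unname(after[cutrow, y]), out$l[cutrow])   # "up" on the piece below t
    nextrow <- qs[out$h[qs] == t_global]
    expect_equal(unname(after[nextrow, y]), 0L)             # "down" on the piece at t
  }
})

test_that("coincident cut points from different symbols are cut once", {
  # fabricated partition: C,G rows flank a 6-long A row whose C- and G-pair
  # thresholds coincide at global offset 5 (in-row offset 2)
  rows <- data.frame(c = c(2L, 3L, 1L, 2L, 3L),
                     h = c(1L, 2L, 3L, 9L, 10L),
                     l = c(1L, 1L, 6L, 1L, 1L))
  empty <- data.frame(i = integer(), j = integer(), tail_i = integer(),
                      head_j = integer(), t = integer())
  ts <- structure(list(
    pairs = list(
      A = empty,
      C = data.frame(i = 1L, j = 4L, tail_i = 1L, head_j = 9L, t = 5L),
      G = data.frame(i = 2L, j = 5L, tail_i = 2L, head_j = 10L, t = 5L),
      T = empty),
    runs_by_symbol = list(
      A = data.frame(run = 3L, h = 3L, tail = 8L),
      C = data.frame(run = c(1L, 4L), h = c(1L, 9L), tail = c(1L, 9L)),
      G = data.frame(run = c(2L, 5L), h = c(2L, 10L), tail = c(2L, 10L)),
      T = data.frame(run = integer(), h = integer(), tail = integer())),
    n_pairs = 2L), class = "threshold_set")
  thr <- map_thresholds_to_rows(ts, rows)
  expect_equal(unname(thr[3L, "C"]), 2L)
  expect_equal(unname(thr[3L, "G"]), 2L)
  out <- split_at_thresholds(rows, ts)
  expect_equal(nrow(out), 6L)              # one shared cut, not two
  expect_equal(out$l[3:4], c(2L, 4L))
})

test_that("splitting stage percentages are plain row-count arithmetic", {
  before <- data.frame(c = 1L, h = 1L, l = 100L)[rep(1L, 100L), ]
  mid <- before[rep(1L, 110L), ]
  after <- mid
  rep100 <- splitting_stats(before, mid, after)
  expect_equal(rep100$pct_threshold, 10)
  expect_equal(rep100$pct_length, 0)
  same <- splitting_stats(before, before, before)
  expect_equal(same$pct_threshold, 0)
  expect_equal(same$pct_length, 0)
})

test_that("neither splitting stage changes any PML", {
  for (seed in c(5, 9)) {
    tx <- text_from_string(random_dna(seed + 300, 600))
    reads <- generate_reads(tx, 8, 40, error_rate = 0.1, seed = seed)
    # diagnostic builds: no threshold split + uncapped lengths, capped only,
    # split only, and the shipped default
    tabs <- list(
      build_move_table(tx, length_bits = Inf, do_threshold_split = FALSE),
      build_move_table(tx, length_bits = Inf, do_threshold_split = TRUE),
      build_move_table(tx, length_bits = 4L, do_threshold_split = FALSE),
      build_move_table(tx, variant = "default")
    )
    for (r in reads) {
      ps <- lapply(tabs, function(tb) compute_pml(tb, r)$pml)
      for (k in 2:4) expect_identical(ps[[k]], ps[[1L]])
    }
  }
})

test_that("adversarial fixtures drive the splitting stages as designed", {
  fx <- adversarial_fixtures()
  # long periodic text: a BWT run longer than 2^11 - 1 forces length-splitting
  tx <- text_from_string(fx$long_run)
  b <- build_suffix_bundle(tx)
  rl <- run_length_encode(b)
  expect_gt(max(rl$runs$l), 2047L)
  tab <- build_move_table(tx, variant = "default")
  expect_gt(tab$split_report$pct_length, 0)

  # periodic fixture: runs of at least 512, minimal r
  b2 <- build_suffix_bundle(text_from_string(fx$periodic))
  expect_gte(max(run_length_encode(b2)$runs$l), 512L)

  # alternating fixture: r = n and no splitting at the default layout
  tx3 <- text_from_string(fx$alternating)
  tab3 <- build_move_table(tx3, variant = "default")
  expect_equal(tab3$r_original, tab3$n)
  expect_equal(tab3$row_count, tab3$r_original)

  # the non-trivial-threshold fixture adds rows in the threshold stage
  tab4 <- build_move_table(text_from_string(fx$nontrivial_threshold))
  expect_gt(tab4$split_report$pct_threshold, 0)
})
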