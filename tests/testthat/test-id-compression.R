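# Blocked (B table + delta) and sampled (S table + scan) id compression.

test_that("per-symbol destination ids are non-decreasing (compression premise)", {
  for (seed in 1:8) {
    tx <- text_from_string(random_dna(seed + 70, 700))
    tab <- build_move_table(tx, variant = "default")
    for (y in 1:4) {
      idx <- which(tab$rows$c == y)
      if (length(idx) > 1L) expect_true(all(diff(tab$rows$xi[idx]) >= 0L))
    }
  }
})

test_that("blocked deltas are checkpoint-relative and resolve to the true ids", {
  tx <- make_tiny()
  tabd <- build_move_table(tx, variant = "default")
  tabb <- build_move_table(tx, variant = "blocked", block_size = 8L)
  expect_equal(nrow(tabb$checkpoints), 1L)  # 6 rows, one block
  # a row that is the first of its symbol in its block has delta 0
  firstC <- which(tabb$rows$c == 2L)[1L]
  expect_equal(tabb$rows$delta[firstC], 0L)
  expect_equal(resolve_id_blocked(tabb, firstC), tabd$rows$xi[firstC])
  # the second C row resolves as checkpoint id + delta
  secondC <- which(tabb$rows$c == 2L)[2L]
  expect_equal(tabb$rows$delta[secondC],
               tabd$rows$xi[secondC] - tabd$rows$xi[firstC])
  for (q in seq_len(tabb$row_count)) {
    expect_equal(resolve_id_blocked(tabb, q), tabd$rows$xi[q])
  }
})

test_that("blocked resolution equals uncompressed ids exhaustively", {
  for (seed in c(2, 13, 27)) {
    n <- sample(200:1500, 1)
    tx <- text_from_string(random_dna(seed + 90, n))
    ref <- build_move_table(tx, variant = "default", length_bits = 10L)
    for (b in c(8L, 2048L)) {
      tab <- build_move_table(tx, variant = "blocked", block_size = b)
      expect_identical(tab$rows$h, ref$rows$h)  # same layout at same bits
      ids <- vapply(seq_len(tab$row_count),
                    function(q) resolve_id_blocked(tab, q), 0L)
      expect_identical(ids, ref$rows$xi)
      expect_true(all(tab$rows$delta >= 0L))
      expect_true(all(tab$rows$delta < 2^23))
    }
  }
})

test_that("sample table covers checkpoints with first-at-or-after ids", {
  tx <- text_from_string(random_dna(5, 400))
  ref <- build_move_table(tx, variant = "default", length_bits = 9L)
  # s = 1: every row is a checkpoint; resolution degenerates to lookup
  tab1 <- build_move_table(tx, variant = "sampled", sample_rate = 1L)
  expect_equal(nrow(tab1$checkpoints), tab1$row_count)
  for (q in sample(tab1$row_count, 25L)) {
    expect_equal(resolve_id_sampled(tab1, q), ref$rows$xi[q])
  }
  # s >= row count: a single checkpoint at the first row
  tabBig <- build_move_table(tx, variant = "sampled",
                             sample_rate = ref$row_count + 10L)
  expect_equal(nrow(tabBig$checkpoints), 1L)
  ids <- vapply(seq_len(tabBig$row_count),
                function(q) resolve_id_sampled(tabBig, q), 0L)
  expect_identical(ids, ref$rows$xi)
  # table size arithmetic
  tab50 <- build_move_table(tx, variant = "sampled", sample_rate = 50L)
  expect_equal(nrow(tab50$checkpoints), ceiling(tab50$row_count / 50))
})

test_that("sampled resolution equals uncompressed ids exhaustively", {
  for (seed in c(4, 18)) {
    n <- sample(300:1500, 1)
    tx <- text_from_string(random_dna(seed + 110, n))
    ref <- build_move_table(tx, variant = "default", length_bits = 9L)
    for (s in c(2L, 5L, 50L)) {
      tab <- build_move_table(tx, variant = "sampled", sample_rate = s)
      ids <- vapply(seq_len(tab$row_count),
                    function(q) resolve_id_sampled(tab, q), 0L)
      expect_identical(ids, ref$rows$xi)
    }
  }
})

test_that("a checkpoint's first matching row resolves with no scan distance", {
  tx <- text_from_string(random_dna(21, 600))
  tab <- build_move_table(tx, variant = "sampled", sample_rate = 5L)
  ref <- build_move_table(tx, variant = "default", length_bits = 9L)
  s <- tab$sample_rate
  for (j in seq_len(nrow(tab$checkpoints))) {
    start <- (j - 1L) * s + 1L
    y <- tab$rows$c[start]
    if (y == 0L) next
    # the checkpoint row itself is the first row of its own symbol at/after
    # the checkpoint, so its stored id must be the row's true destination
    expect_equal(unname(tab$checkpoints[j, y]), ref$rows$xi[start])
    expect_equal(resolve_id_sampled(tab, start), ref$rows$xi[start])
  }
})

test_that("delta overflow halves the block size until every delta fits", {
  rows <- data.frame(c = rep(c(1L, 2L), 8L), h = seq(1L, 16L), l = rep(1L, 16L))
  xi <- rep(1L, 16L)
  xi[rows$c == 1L] <- c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L)
  xi[rows$c == 2L] <- c(9L, 10L, 11L, 12L, 13L, 14L, 15L, 16L)
  # with delta_bits = 2, a block of 16 rows has deltas up to 7 -> must halve
  suppressMessages({
    bt <- build_block_table(rows, xi, terminator_row = 0L, b = 16L,
                            delta_bits = 2L)
  })
  expect_lt(bt$b, 16L)
  expect_true(all(bt$delta < 4L))
  # and the monotonicity guard rejects shuffled ids
  expect_error(build_block_table(rows, rev(xi), terminator_row = 0L, b = 4L),
               "non-decreasing")
})
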