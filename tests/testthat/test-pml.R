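# Pseudo Matching Length queries and the matching-statistics oracle.

test_that("the worked micro-trace and matching-statistics examples hold", {
  tx <- make_tiny()
  tab <- build_move_table(tx)
  expect_equal(compute_pml(tab, "CA")$pml, c(1L, 0L))
  expect_equal(pml_oracle(tx, "CA"), c(1L, 0L))
  expect_equal(matching_statistics_naive(tx, "CA"), c(2L, 1L))
  expect_equal(matching_statistics_naive(tx, "ACACG"), c(5L, 4L, 3L, 2L, 1L))
})

test_that("structural PML invariants hold: last zero, increments of one", {
  for (seed in 1:10) {
    tx <- text_from_string(random_dna(seed + 130, 500))
    tab <- build_move_table(tx)
    reads <- generate_reads(tx, 5, 60, error_rate = 0.15, seed = seed)
    for (r in reads) {
      pml <- compute_pml(tab, r)$pml
      m <- length(pml)
      expect_equal(pml[m], 0L)
      expect_true(all(pml[-m] == 0L | pml[-m] == pml[-1L] + 1L))
      expect_true(all(pml >= 0L & pml < m))
    }
  }
})

test_that("PML lower-bounds the matching statistics and its witnesses occur in T", {
  for (seed in 1:12) {
    n <- sample(100:800, 1)
    tx <- text_from_string(random_dna(seed + 160, n))
    tab <- build_move_table(tx)
    tstr <- sub("\\$$", "", text_as_string(tx))
    reads <- generate_reads(tx, 3, min(50, n - 1), error_rate = 0.1, seed = seed)
    for (r in reads) {
      pml <- compute_pml(tab, r)$pml
      ms <- matching_statistics_naive(tx, r)
      expect_true(all(pml <= ms))
      for (k in which(pml > 0L)) {
        expect_true(grepl(substr(r, k, k + pml[k] - 1L), tstr, fixed = TRUE))
      }
    }
  }
})

test_that("the move-table PML equals the global-offset step oracle", {
  for (seed in 1:8) {
    tx <- text_from_string(random_dna(seed + 190, 300))
    tab <- build_move_table(tx)
    reads <- generate_reads(tx, 4, 30, error_rate = 0.2, seed = seed)
    for (r in reads) {
      expect_identical(compute_pml(tab, r)$pml, pml_oracle(tx, r))
    }
  }
})

test_that("exact substrings of the text reach the full matching-statistics ramp", {
  tx <- text_from_string(random_dna(8, 400))
  tab <- build_move_table(tx)
  tstr <- sub("\\$$", "", text_as_string(tx))
  for (start in c(1L, 100L, 200L)) {
    p <- substr(tstr, start, start + 29L)
    m <- nchar(p)
    ms <- matching_statistics_naive(tx, p)
    expect_equal(ms, seq.int(m, 1L))          # the whole suffix always occurs
    pml <- compute_pml(tab, p)$pml
    expect_true(all(pml <= ms))
    # once the walk locks onto an occurrence the ramp is complete: the PML
    # profile of an exact substring is a tail-aligned sub-ramp on the left
    expect_identical(pml, pml_oracle(tx, p))
    expect_gte(pml[1L], m %/% 2L)             # fixture-level: most of the ramp
  }
})

test_that("symbols absent from the text yield zero PMLs without moving", {
  tx <- text_from_string("ACACAACC")   # G and T absent
  tab <- build_move_table(tx)
  expect_equal(compute_pml(tab, "GTGT")$pml, rep(0L, 4L))
  mixed <- compute_pml(tab, "CAGT")$pml
  expect_equal(mixed[3:4], c(0L, 0L))
  expect_true(all(mixed <= matching_statistics_naive(tx, "CAGT")))
})

test_that("all three variants produce bitwise-identical PML arrays", {
  for (seed in c(6, 14)) {
    tx <- text_from_string(random_dna(seed + 230, 700))
    tabs <- list(
      build_move_table(tx, variant = "default"),
      build_move_table(tx, variant = "blocked", block_size = 8L),
      build_move_table(tx, variant = "blocked", block_size = 2048L),
      build_move_table(tx, variant = "sampled", sample_rate = 2L),
      build_move_table(tx, variant = "sampled", sample_rate = 50L),
      build_move_table(tx, variant = "sampled", sample_rate = 200L))
    reads <- generate_reads(tx, 6, 50, error_rate = 0.1, seed = seed)
    for (r in reads) {
      ps <- lapply(tabs, function(tb) compute_pml(tb, r)$pml)
      for (k in 2:length(ps)) expect_identical(ps[[k]], ps[[1L]])
    }
  }
})

test_that("batch queries are order-preserving, stateless and stream-safe", {
  tx <- text_from_string(random_dna(41, 500))
  tab <- build_move_table(tx)
  expect_equal(compute_pml_batch(tab, character()), list())
  reads <- generate_reads(tx, 30, 40, error_rate = 0.05, seed = 2)
  reads <- c(reads, reads[1L])  # duplicate read
  batch <- compute_pml_batch(tab, reads)
  expect_equal(length(batch), length(reads))
  expect_equal(vapply(batch, `[[`, "", "name"), names(reads))
  singles <- lapply(seq_along(reads),
                    function(i) compute_pml(tab, reads[[i]])$pml)
  for (i in seq_along(reads)) expect_identical(batch[[i]]$pml, singles[[i]])
  expect_identical(batch[[length(reads)]]$pml, batch[[1L]]$pml)
  # malformed records are reported and skipped
  bad <- c(reads[1:2], broken = NA_character_)
  expect_warning(res <- compute_pml_batch(tab, bad), "malformed")
  expect_equal(length(res), 2L)
})

test_that("reads from the indexed text score far above reads from unrelated text", {
  spec <- pangenome_spec(base_length = 3000L, n_haplotypes = 5L, seed = 77L)
  seqs <- generate_pangenome(spec)
  tx <- pangenome_text(seqs)
  tab <- build_move_table(tx)
  own <- generate_reads(seqs, 15, 100, error_rate = 0, seed = 10)
  other <- generate_reads(
    stats::setNames(random_dna(1234, 5000), "unrelated"), 15, 100,
    error_rate = 0, seed = 11)
  mean_own <- mean(unlist(lapply(compute_pml_batch(tab, own), `[[`, "pml")))
  mean_other <- mean(unlist(lapply(compute_pml_batch(tab, other), `[[`, "pml")))
  expect_gt(mean_own, 4 * mean_other)
})
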