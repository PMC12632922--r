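# Compressed representations of the destination-row id column.
#
# The compression premise: LF stably sorts symbols, so over the rows of any
# one symbol the destination id is non-decreasing. The blocked design stores,
# per fixed-size block and per symbol, the id of the first row of that symbol
# at or after the block start (the B table) and keeps only the small delta
# per row. The sampled design stores the same checkpoints every s rows (the
# S table) and drops the per-row column entirely, reconstructing ids at query
# time by scanning: count the BWT length of same-symbol rows between the
# checkpoint's first matching row and the query row, then fast-forward that
# distance from the checkpointed destination.

#' Build the blocked checkpoint (B) table and per-row deltas
#'
#' Divides the move table into blocks of `b` rows. For block `i'` and symbol
#' `y`, the checkpoint holds the destination id of the first `y`-row at or
#' after row `i' * b` within the block (0 when the block has no `y`-row;
#' provably never dereferenced, since any query row of symbol `y` in the
#' block is itself such a row). Each row stores only
#' `delta = xi - B[block][c]`, which is non-negative by the monotonicity of
#' ids per symbol. If any delta overflows `delta_bits`, the block size is
#' halved and the table rebuilt.
#'
#' @param rows final row data.frame (`c`, `h`, `l`)
#' @param xi true destination ids from the uncompressed build
#' @param terminator_row index of the sentinel row (excluded: its id is the
#'   constant 1 and is special-cased at resolution)
#' @param b block size in rows
#' @param delta_bits width of the per-row delta field (23 in the 6-byte layout)
#' @return list with `checkpoints` (matrix blocks x 4), `delta` (integer per
#'   row; 0 at the terminator row), and the final `b`
#' @export
build_block_table <- function(rows, xi, terminator_row, b, delta_bits = 23L) {
  b <- as.integer(b)
  stopifnot(b >= 1L)
  rc <- nrow(rows)
  assert_ids_monotone(rows$c, xi, terminator_row)
  repeat {
    nblocks <- (rc + b - 1L) %/% b
    checkpoints <- matrix(0L, nrow = nblocks, ncol = SIGMA,
                          dimnames = list(NULL, ALPHABET))
    delta <- integer(rc)
    overflow <- FALSE
    bi <- (seq_len(rc) - 1L) %/% b + 1L
    for (y in seq_len(SIGMA)) {
      idx <- which(rows$c == y)
      if (!length(idx)) next
      first_in_block <- !duplicated(bi[idx])
      checkpoints[bi[idx][first_in_block], y] <- xi[idx[first_in_block]]
      delta[idx] <- xi[idx] - checkpoints[bi[idx], y]
    }
    if (any(delta < 0L)) stop("negative delta: id monotonicity violated")
    if (max(delta) < 2^delta_bits) {
      return(list(checkpoints = checkpoints, delta = delta, b = b))
    }
    if (b == 1L) {
      stop("delta overflows ", delta_bits, " bits even at block size 1: ",
           "layout cannot represent this index")
    }
    b <- max(1L, b %/% 2L)
    message("delta overflow: halving block size to b = ", b)
  }
}

# per-symbol non-decreasing id assertion (the compression premise)
assert_ids_monotone <- function(c, xi, terminator_row) {
  for (y in seq_len(SIGMA)) {
    idx <- which(c == y)
    if (length(idx) > 1L && any(diff(xi[idx]) < 0L)) {
      stop("destination ids not non-decreasing for symbol ", ALPHABET[y])
    }
  }
  invisible(TRUE)
}

#' Resolve a destination id in a blocked-variant table
#'
#' `id = B[block(q)][c(q)] + delta(q)`; the terminator row resolves to the
#' constant 1 (the LF image of the sentinel is BWT offset 1, the head of the
#' first row).
#'
#' @param table a blocked-variant move table
#' @param q row index
#' @return destination row id
#' @export
resolve_id_blocked <- function(table, q) {
  stopifnot(table$variant == "blocked")
  if (q == table$terminator_row) return(1L)
  bi <- (q - 1L) %/% table$block_size + 1L
  unname(table$checkpoints[bi, table$rows$c[q]] + table$rows$delta[q])
}

#' Build the sampled checkpoint (S) table
#'
#' Checkpoints sit every `s` rows. For checkpoint `j` (covering rows starting
#' at `(j-1)*s + 1`) and symbol `y`, the table holds the destination id of
#' the first `y`-row at or after the checkpoint row anywhere in the table
#' (0 when no such row exists; never dereferenced). The per-row id column is
#' then dropped.
#'
#' @inheritParams build_block_table
#' @param s sampling rate in rows
#' @return list with `checkpoints` (matrix ceiling(rows/s) x 4) and `s`
#' @export
build_sample_table <- function(rows, xi, terminator_row, s) {
  s <- as.integer(s)
  stopifnot(s >= 1L)
  rc <- nrow(rows)
  assert_ids_monotone(rows$c, xi, terminator_row)
  nck <- (rc + s - 1L) %/% s
  starts <- (seq_len(nck) - 1L) * s + 1L
  checkpoints <- matrix(0L, nrow = nck, ncol = SIGMA,
                        dimnames = list(NULL, ALPHABET))
  for (y in seq_len(SIGMA)) {
    idx <- which(rows$c == y)
    if (!length(idx)) next
    pos <- findInterval(starts - 1L, idx) + 1L  # first y-row index >= start
    has <- pos <= length(idx)
    checkpoints[has, y] <- xi[idx[pos[has]]]
  }
  list(checkpoints = checkpoints, s = s)
}

#' Resolve a destination id in a sampled-variant table by scanning
#'
#' Let `j` be the checkpoint covering row `q` and `y` the row's symbol. The
#' scan finds the first `y`-row `i0` at or after the checkpoint row, sums the
#' BWT lengths `d` of `y`-rows in `[i0, q)`, and fast-forwards
#' `v = f[i0] + d` from the checkpointed destination `S[j][y]`; the row
#' reached is the destination id of `q`. When no `y`-row precedes `q` in the
#' window, `i0 = q` and the checkpointed id is already the answer.
#'
#' @param table a sampled-variant move table
#' @param q row index
#' @return destination row id
#' @export
resolve_id_sampled <- function(table, q) {
  stopifnot(table$variant == "sampled")
  if (q == table$terminator_row) return(1L)
  y <- table$rows$c[q]
  s <- table$sample_rate
  j <- (q - 1L) %/% s + 1L
  start <- (j - 1L) * s + 1L
  lens <- table$rows$l
  scanned <- 0L
  if (start < q) {
    win <- start:(q - 1L)
    ymask <- table$rows$c[win] == y
    scanned <- length(win)
    if (any(ymask)) {
      i0 <- win[which(ymask)[1L]]
      d <- sum(lens[win][ymask])
    } else {
      i0 <- q
      d <- 0L
    }
  } else {
    i0 <- q
    d <- 0L
  }
  row <- unname(table$checkpoints[j, y])
  if (row == 0L) stop("dereferenced an empty checkpoint: corrupt S table")
  v <- table$rows$f[i0] + d
  while (v >= lens[row]) {
    v <- v - lens[row]
    row <- row + 1L
    if (row > table$row_count) stop("sampled-id fast-forward ran past the last row")
  }
  .query_counters$id_scans <- .query_counters$id_scans + 1
  .query_counters$id_scan_rows <- .query_counters$id_scan_rows + scanned
  row
}
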