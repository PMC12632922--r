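# The move structure.
#
# One table, one navigation code path. Each row covers a sub-run of the BWT
# and stores its symbol c, length l, the offset f of the LF image of the row
# head within its destination row, the destination row id (materialised
# directly in the default variant, as a checkpoint delta in the blocked
# variant, or reconstructed by scanning in the sampled variant), and one
# trivialised up/down threshold bit per mismatch symbol.
#
# A BWT offset is a pair (u, v): row index u (1-based) and in-row offset v
# (0-based). LF of (u, v) is computed as v'' = f[u] + v starting at the
# resolved destination row, then fast-forwarding row by row while v''
# overflows the current row.

# package-internal counters for fast-forward / scan statistics
.query_counters <- new.env(parent = emptyenv())

reset_query_counters <- function() {
  .query_counters$lf_calls <- 0
  .query_counters$ff_steps <- 0
  .query_counters$repositions <- 0
  .query_counters$reposition_rows <- 0
  .query_counters$id_scans <- 0
  .query_counters$id_scan_rows <- 0
  invisible(NULL)
}
reset_query_counters()

#' Query-time work counters
#'
#' Cumulative counts of LF calls, fast-forward steps, reposition scans and
#' sampled-id scans since the last reset; `stats` reports the means.
#' @param reset reset the counters after reading?
#' @return named list of counters
#' @export
query_counters <- function(reset = FALSE) {
  out <- as.list(.query_counters)
  if (reset) reset_query_counters()
  out
}

#' Construct a BWT position
#' @param u row index (1-based)
#' @param v in-row offset (0-based, `< l[u]`)
#' @return a `bwt_position` (named integer pair)
#' @export
bwt_position <- function(u, v) {
  structure(c(u = as.integer(u), v = as.integer(v)), class = "bwt_position")
}

#' Convert a BWT position to a global BWT offset
#' @param table a move table
#' @param pos a [bwt_position()]
#' @return 1-based global BWT offset
#' @export
position_to_offset <- function(table, pos) {
  table$rows$h[pos[["u"]]] + pos[["v"]]
}

#' Convert a global BWT offset to a BWT position
#' @param table a move table
#' @param i 1-based global BWT offset
#' @return a [bwt_position()]
#' @export
offset_to_position <- function(table, i) {
  stopifnot(i >= 1L, i <= table$n)
  u <- findInterval(i, table$rows$h)
  bwt_position(u, i - table$rows$h[u])
}

#' Build a move-structure index
#'
#' Pipeline: suffix bundle, RLBWT, thresholds, thresholds-splitting,
#' length-splitting, then pointer computation on the final row set. The LF
#' image of every row head is obtained from the rank formula (LF is stable,
#' so same-symbol head images are consecutive); the destination row is
#' located by binary search of those images over the row heads.
#'
#' @param text a [pangenome_text()] object
#' @param variant `"default"` (explicit 36-bit id per row), `"blocked"`
#'   (checkpoint B table plus per-row delta) or `"sampled"` (S table only;
#'   ids reconstructed by scanning at query time)
#' @param length_bits width of the length/offset bit fields; defaults to the
#'   shipped layout of the chosen variant (11, 10, 9). Use `Inf` to disable
#'   length-splitting (diagnostic builds only; such tables cannot be
#'   serialized).
#' @param do_threshold_split cut rows so all thresholds become trivial
#'   (required for serialization); `FALSE` keeps non-trivial thresholds
#'   in-memory for diagnostics
#' @param block_size blocked variant: rows per checkpoint block (halved
#'   automatically until every delta fits its 23-bit field)
#' @param sample_rate sampled variant: rows between checkpoints
#' @param keep_bundle retain the suffix bundle in the result (used by
#'   verification; large)
#' @param bundle optional pre-built [build_suffix_bundle()] for `text`,
#'   reused instead of rebuilding (they must match)
#' @return an object of class `move_table`; see Details
#' @details The returned list contains `rows` (data.frame `c`, `h`, `l`, `f`,
#'   plus `xi` or `delta` by variant), `thr` (row-relative threshold matrix,
#'   trivial after thresholds-splitting), `variant`, `n`, `r_original`,
#'   `row_count`, `terminator_row`, `layout`, `split_report`,
#'   `symbol_counts`, and for blocked/sampled variants the checkpoint matrix
#'   `checkpoints` with attribute block size / sampling rate.
#' @examples
#' tab <- build_move_table(text_from_string("ACACGT"))
#' tab$row_count  # 6
#' @export
build_move_table <- function(text,
                             variant = c("default", "blocked", "sampled"),
                             length_bits = NULL,
                             do_threshold_split = TRUE,
                             block_size = 2048L,
                             sample_rate = 50L,
                             keep_bundle = FALSE,
                             bundle = NULL) {
  variant <- match.arg(variant)
  if (is.null(length_bits)) {
    length_bits <- switch(variant, default = 11L, blocked = 10L, sampled = 9L)
  }
  if (is.null(bundle)) bundle <- build_suffix_bundle(text)
  rl <- run_length_encode(bundle)
  ts <- compute_thresholds(bundle, rl)
  rows0 <- rl$runs
  rows1 <- if (do_threshold_split) split_at_thresholds(rows0, ts) else rows0
  l_max <- if (is.finite(length_bits)) 2L^as.integer(length_bits) - 1L else Inf
  rows2 <- if (is.finite(l_max)) split_by_length(rows1, l_max) else rows1
  report <- splitting_stats(rows0, rows1, rows2)

  rows <- rows2
  rc <- nrow(rows)
  thr <- map_thresholds_to_rows(ts, rows)

  # pointers: pi = LF(head) via per-symbol consecutive ranks, then binary search
  pi <- integer(rc)
  for (y in 0:SIGMA) {
    idx <- which(rows$c == y)
    if (!length(idx)) next
    ypos <- which(bundle$bwt == y)
    rank_at_head <- findInterval(rows$h[idx], ypos)
    pi[idx] <- bundle$c_counts[[y + 1L]] + rank_at_head
  }
  xi <- findInterval(pi, rows$h)
  f <- pi - rows$h[xi]

  terminator_row <- findInterval(which(bundle$bwt == SENTINEL_CODE), rows$h)
  rows$c[terminator_row] <- SENTINEL_CODE
  # the sentinel row's A-direction is defined by a load-reconstructible rule:
  # down iff an A-row exists below it (its 3 serialized bits cover C,G,T only)
  thr[terminator_row, 1L] <- terminator_a_direction(rows, terminator_row)

  symbol_counts <- vapply(seq_len(SIGMA),
                          function(y) sum(rows$l[rows$c == y]), 0)
  names(symbol_counts) <- ALPHABET

  tab <- structure(list(
    variant = variant,
    n = bundle$n,
    r_original = rl$r,
    row_count = rc,
    rows = data.frame(c = rows$c, h = rows$h, l = rows$l, f = f),
    thr = thr,
    terminator_row = terminator_row,
    layout = list(length_bits = as.integer(if (is.finite(length_bits)) length_bits else NA),
                  id_bits = 36L, delta_bits = 23L, checkpoint_id_bytes = 5L),
    split_report = report,
    symbol_counts = symbol_counts,
    substitutions = text$substitutions
  ), class = "move_table")

  if (variant == "default") {
    tab$rows$xi <- xi
  } else if (variant == "blocked") {
    bt <- build_block_table(rows, xi, terminator_row, block_size,
                            delta_bits = tab$layout$delta_bits)
    tab$rows$delta <- bt$delta
    tab$checkpoints <- bt$checkpoints
    tab$block_size <- bt$b
  } else {
    st <- build_sample_table(rows, xi, terminator_row, sample_rate)
    tab$checkpoints <- st$checkpoints
    tab$sample_rate <- as.integer(sample_rate)
  }
  if (keep_bundle) tab$bundle <- bundle
  tab
}

# rule for the sentinel row's A-direction bit: 0 (down) iff an A-row exists
# below the terminator; recomputable from the row array alone after load
terminator_a_direction <- function(rows, terminator_row) {
  below <- rows$c[seq_len(nrow(rows)) > terminator_row] == 1L
  if (any(below)) 0L else rows$l[terminator_row]
}

#' @export
print.move_table <- function(x, ...) {
  extra <- switch(x$variant,
    default = "",
    blocked = sprintf(", b = %d (%d checkpoints)", x$block_size, nrow(x$checkpoints)),
    sampled = sprintf(", s = %d (%d checkpoints)", x$sample_rate, nrow(x$checkpoints)))
  cat(sprintf("move_table [%s]: n = %d, r = %d, rows = %d%s\n",
              x$variant, x$n, x$r_original, x$row_count, extra))
  invisible(x)
}

# resolve the destination row id of row u under the table's variant
resolve_id <- function(table, u) {
  switch(table$variant,
         default = table$rows$xi[u],
         blocked = resolve_id_blocked(table, u),
         sampled = resolve_id_sampled(table, u))
}

#' One LF-mapping step on the move structure
#'
#' Computes `v'' = f[u] + v`, starts at the destination row of `u` (resolved
#' per variant) and fast-forwards row by row while `v''` is at least the
#' current row length. Equals [lf_direct()] on the corresponding global
#' offsets.
#'
#' @param table a move table
#' @param pos a [bwt_position()]
#' @return a [bwt_position()]
#' @export
move_lf <- function(table, pos) {
  u <- pos[["u"]]
  v <- pos[["v"]]
  stopifnot(u >= 1L, u <= table$row_count, v >= 0L, v < table$rows$l[u])
  v2 <- table$rows$f[u] + v
  row <- resolve_id(table, u)
  lens <- table$rows$l
  ff <- 0L
  while (v2 >= lens[row]) {
    v2 <- v2 - lens[row]
    row <- row + 1L
    ff <- ff + 1L
    if (row > table$row_count) stop("fast-forward ran past the last row: corrupt index")
  }
  .query_counters$lf_calls <- .query_counters$lf_calls + 1
  .query_counters$ff_steps <- .query_counters$ff_steps + ff
  bwt_position(row, v2)
}

#' Symbol at a BWT position
#'
#' Returns the row symbol; the exact terminator position reports the sentinel
#' (code 0), which never matches a query symbol.
#'
#' @param table a move table
#' @param pos a [bwt_position()]
#' @return symbol code (0 sentinel, 1..4 A,C,G,T)
#' @export
char_at <- function(table, pos) {
  table$rows$c[pos[["u"]]]
}

#' Reposition to the nearest row of a given symbol on a mismatch
#'
#' Direction is chosen by the current row's threshold for `c` compared with
#' the in-row offset (`v < t` repositions up; with trivialised thresholds the
#' stored bit alone decides). Scanning up lands on the tail of the nearest
#' `c`-row above; scanning down on the head of the nearest `c`-row below. The
#' terminator row never matches (its symbol code is 0).
#'
#' @param table a move table
#' @param pos a [bwt_position()]
#' @param c mismatch symbol (code or character), must occur in the text
#' @return a [bwt_position()] whose row symbol is `c`
#' @export
reposition <- function(table, pos, c) {
  c <- as_symbol_code(c)
  stopifnot(c >= 1L, c <= SIGMA)
  if (table$symbol_counts[[c]] == 0) stop("symbol not indexed: ", ALPHABET[c])
  u <- pos[["u"]]
  v <- pos[["v"]]
  if (!is.na(table$rows$c[u]) && table$rows$c[u] == c) {
    stop("reposition called on a matching row (contract: mismatch only)")
  }
  t <- table$thr[u, c]
  up <- v < t
  cs <- table$rows$c
  if (up) {
    cand <- which(cs[seq_len(u - 1L)] == c)
    if (!length(cand)) stop("no row with symbol ", ALPHABET[c], " above row ", u,
                            ": corrupt threshold direction")
    w <- cand[length(cand)]
    out <- bwt_position(w, table$rows$l[w] - 1L)
  } else {
    cand <- which(cs[seq.int(u + 1L, length.out = table$row_count - u)] == c)
    if (!length(cand)) stop("no row with symbol ", ALPHABET[c], " below row ", u,
                            ": corrupt threshold direction")
    w <- u + cand[1L]
    out <- bwt_position(w, 0L)
  }
  .query_counters$repositions <- .query_counters$repositions + 1
  .query_counters$reposition_rows <- .query_counters$reposition_rows + abs(w - u)
  out
}

#' Verify a move table against the brute-force LF oracle
#'
#' Recomputes the suffix bundle from the table's text (or uses a supplied
#' bundle), resolves every row id per variant, and checks that the move-table
#' LF equals the rank-formula LF at every BWT offset, and that an n-step LF
#' walk from the sentinel row reconstructs the text.
#'
#' @param table a move table
#' @param text the `pangenome_text` the table was built from
#' @param bundle optional pre-built [build_suffix_bundle()] result
#' @return invisibly `TRUE`; stops with a message on any mismatch
#' @export
verify_index <- function(table, text, bundle = NULL) {
  if (is.null(bundle)) bundle <- build_suffix_bundle(text)
  if (bundle$n != table$n) stop("text length differs from indexed length")
  lf_oracle <- lf_direct_all(bundle)
  lf_table <- move_lf_all(table)
  bad <- which(lf_table != lf_oracle)
  if (length(bad)) {
    stop("move LF disagrees with the LF oracle at ", length(bad),
         " offset(s), first at ", bad[1L])
  }
  rec <- reconstruct_text(bundle)
  if (!identical(rec, text$symbols)) stop("LF walk failed to reconstruct the text")
  invisible(TRUE)
}

# vectorised move-structure LF over all global offsets (verification sweeps);
# resolves all row ids per variant first, then fast-forwards all offsets in
# lockstep (few iterations: overflow beyond the destination row is rare)
move_lf_all <- function(table) {
  rows <- table$rows
  ids <- resolve_id_all(table)
  # expand per-offset: offset i in row u at in-row v
  u <- rep.int(seq_len(table$row_count), rows$l)
  v <- sequence(rows$l) - 1L
  v2 <- rows$f[u] + v
  row <- ids[u]
  repeat {
    over <- v2 >= rows$l[row]
    if (!any(over)) break
    v2[over] <- v2[over] - rows$l[row[over]]
    row[over] <- row[over] + 1L
    if (any(row > table$row_count)) stop("fast-forward ran past the last row")
  }
  rows$h[row] + v2
}

# resolve every row's destination id per variant (vectorised per symbol)
resolve_id_all <- function(table) {
  switch(table$variant,
    default = table$rows$xi,
    blocked = {
      rc <- table$row_count
      bi <- (seq_len(rc) - 1L) %/% table$block_size + 1L
      ids <- integer(rc)
      for (y in seq_len(SIGMA)) {
        idx <- which(table$rows$c == y)
        if (length(idx)) ids[idx] <- table$checkpoints[bi[idx], y] + table$rows$delta[idx]
      }
      ids[table$terminator_row] <- 1L
      ids
    },
    sampled = vapply(seq_len(table$row_count),
                     function(q) resolve_id_sampled(table, q), 0L)
  )
}
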