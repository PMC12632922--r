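# Run splitting.
#
# Two transforms applied to the run partition before pointers are computed:
#   1. thresholds-splitting: cut every row at each distinct strictly-interior
#      threshold offset, so that afterwards every row-relative threshold sits
#      at 0 or at the row length and a single up/down bit per symbol suffices;
#   2. length-splitting: cap row length at l_max = 2^length_bits - 1 so the
#      length and offset columns fit a narrow bit field.
# Both preserve the BWT partition and never change query results; pointers
# (f, xi) are computed once afterwards on the final row set.

#' Split configuration for a move-table build
#'
#' @param length_bits bit width of the length and offset columns; the shipped
#'   layouts use 11 (default variant), 10 (blocked) and 9 (sampled)
#' @param do_threshold_split cut rows at non-trivial thresholds first?
#' @return a `split_config` list with `length_bits`, `l_max`
#'   (`2^length_bits - 1`) and `do_threshold_split`
#' @export
split_config <- function(length_bits = 11L, do_threshold_split = TRUE) {
  length_bits <- as.integer(length_bits)
  stopifnot(length_bits >= 1L)
  structure(list(length_bits = length_bits,
                 l_max = 2L^length_bits - 1L,
                 do_threshold_split = do_threshold_split),
            class = "split_config")
}

# cut one row (h, l) at sorted interior offsets; returns lengths of pieces
cut_lengths <- function(l, cuts) {
  diff(c(0L, cuts, l))
}

#' Cut rows at their non-trivial thresholds
#'
#' Each row is cut at every distinct strictly-interior row-relative threshold
#' it holds (up to sigma - 1 cuts per row; coincident cut points from
#' different symbols are cut once). In the output every row-relative
#' threshold is trivial (0 or the row length), so each fits a single up/down
#' bit. At most one new row per adjacent same-symbol run pair is added, so the
#' output has at most `r + n_pairs <= 2 r` rows.
#'
#' @param rows data.frame with columns `c`, `h`, `l` partitioning the BWT
#' @param ts a [compute_thresholds()] result for the same text
#' @return a row data.frame of the same shape with every threshold trivial
#' @export
split_at_thresholds <- function(rows, ts) {
  thr <- map_thresholds_to_rows(ts, rows)
  interior <- thr > 0L & thr < rows$l  # NA own-symbol entries drop out below
  has_cut <- which(rowSums(interior, na.rm = TRUE) > 0L)
  if (!length(has_cut)) return(rows)
  pieces_c <- vector("list", nrow(rows))
  pieces_l <- vector("list", nrow(rows))
  pieces_c[] <- as.list(rows$c)
  pieces_l[] <- as.list(rows$l)
  for (q in has_cut) {
    v <- thr[q, ]
    cuts <- sort(unique(v[!is.na(v) & v > 0L & v < rows$l[q]]))
    pieces_l[[q]] <- cut_lengths(rows$l[q], cuts)
    pieces_c[[q]] <- rep(rows$c[q], length(cuts) + 1L)
  }
  l <- unlist(pieces_l)
  out <- data.frame(c = unlist(pieces_c),
                    h = cumsum(c(1L, l[-length(l)])),
                    l = l)
  rownames(out) <- NULL
  out
}

#' Cap row lengths by splitting long rows
#'
#' A row of length `l > l_max` becomes `ceiling(l / l_max)` sub-rows, all but
#' the last of length `l_max` and the last holding the remainder; exact
#' multiples produce no zero-length remainder row.
#'
#' @param rows data.frame with columns `c`, `h`, `l` partitioning the BWT
#' @param l_max maximum allowed row length (`>= 1`)
#' @return a row data.frame with every length `<= l_max`
#' @export
split_by_length <- function(rows, l_max) {
  stopifnot(l_max >= 1L)
  if (all(rows$l <= l_max)) return(rows)
  n_pieces <- (rows$l + l_max - 1L) %/% l_max
  c_out <- rep(rows$c, n_pieces)
  l_out <- rep(l_max, sum(n_pieces))
  # last piece of each original row holds the remainder (l_max on exact division)
  last_idx <- cumsum(n_pieces)
  rem <- rows$l - (n_pieces - 1L) * l_max
  l_out[last_idx] <- rem
  out <- data.frame(c = c_out,
                    h = cumsum(c(1L, l_out[-length(l_out)])),
                    l = l_out)
  rownames(out) <- NULL
  out
}

#' Row-count statistics across the splitting stages
#'
#' Reports the metric used to characterise splitting cost: rows added by
#' thresholds-splitting as a percentage of the original run count, and rows
#' added by length-splitting as a percentage of the post-threshold-split
#' count.
#'
#' @param before rows before any splitting (the maximal-run partition)
#' @param mid rows after thresholds-splitting
#' @param after rows after length-splitting
#' @return a `split_report` list with `r_original`,
#'   `rows_after_threshold_split`, `rows_after_length_split`, `pct_threshold`,
#'   `pct_length`
#' @export
splitting_stats <- function(before, mid, after) {
  r0 <- nrow(before)
  r1 <- nrow(mid)
  r2 <- nrow(after)
  stopifnot(r1 >= r0, r2 >= r1)
  structure(list(r_original = r0,
                 rows_after_threshold_split = r1,
                 rows_after_length_split = r2,
                 pct_threshold = 100 * (r1 - r0) / r0,
                 pct_length = 100 * (r2 - r1) / r1),
            class = "split_report")
}

#' @export
print.split_report <- function(x, ...) {
  cat(sprintf(
    "split_report: r = %d -> %d (+%.2f%% thresholds) -> %d (+%.2f%% length)\n",
    x$r_original, x$rows_after_threshold_split, x$pct_threshold,
    x$rows_after_length_split, x$pct_length
  ))
  invisible(x)
}
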