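# Matching-statistics thresholds.
#
# For two adjacent runs of the same symbol c (no intervening c-run), the
# threshold t is a BWT offset in (tail_i, head_j] splitting the gap into an
# upper part (closer right-context to the earlier run's tail) and a lower part
# (closer to the later run's head). On a mismatch at offset k the query
# repositions up to the earlier tail when k < t and down to the later head
# when k >= t. We pick the leftmost position of the minimum LCP value in
# (tail_i, head_j]; a range-minimum argument shows this always satisfies both
# defining LCP conditions, and verify_threshold() re-checks them by brute
# force in the test suite.

#' Compute thresholds for every adjacent same-symbol run pair
#'
#' @param bundle a [build_suffix_bundle()] result
#' @param rlbwt a [run_length_encode()] result over the same text
#' @return an object of class `threshold_set`: a list with `pairs`, a
#'   per-symbol list (names A,C,G,T) of data.frames with columns `i`, `j`
#'   (global run indices of the earlier/later run), `tail_i`, `head_j`
#'   (BWT offsets), and `t` (the chosen threshold offset); and `n_pairs`.
#' @examples
#' tx <- text_from_string("ACACGT")
#' b <- build_suffix_bundle(tx)
#' ts <- compute_thresholds(b, run_length_encode(b))
#' ts$pairs$C$t  # 4
#' @export
compute_thresholds <- function(bundle, rlbwt) {
  runs <- rlbwt$runs
  lcp <- bundle$lcp
  pairs <- vector("list", SIGMA)
  names(pairs) <- ALPHABET
  for (y in seq_len(SIGMA)) {
    idx <- which(runs$c == y)
    if (length(idx) < 2L) {
      pairs[[y]] <- data.frame(i = integer(), j = integer(),
                               tail_i = integer(), head_j = integer(),
                               t = integer())
      next
    }
    i <- idx[-length(idx)]
    j <- idx[-1L]
    tail_i <- runs$h[i] + runs$l[i] - 1L
    head_j <- runs$h[j]
    t <- integer(length(i))
    for (k in seq_along(i)) {
      win <- (tail_i[k] + 1L):head_j[k]
      t[k] <- tail_i[k] + which.min(lcp[win])
    }
    pairs[[y]] <- data.frame(i = i, j = j, tail_i = tail_i,
                             head_j = head_j, t = t)
  }
  runs_by_symbol <- lapply(seq_len(SIGMA), function(y) {
    idx <- which(runs$c == y)
    data.frame(run = idx, h = runs$h[idx],
               tail = runs$h[idx] + runs$l[idx] - 1L)
  })
  names(runs_by_symbol) <- ALPHABET
  structure(list(pairs = pairs, runs_by_symbol = runs_by_symbol,
                 n_pairs = sum(vapply(pairs, nrow, 0L))),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("threshold_set: %d adjacent same-symbol run pairs\n", x$n_pairs))
  invisible(x)
}

#' Verify a threshold against the defining LCP conditions (brute force)
#'
#' Checks, by direct range-minimum computation over the LCP array, that for
#' all `k` in `(tail_i, t)` the LCP of row `k` with the earlier run's tail is
#' at least its LCP with the later run's head, and that for all `k` in
#' `[t, head_j)` the inequality is reversed.
#'
#' @param bundle a [build_suffix_bundle()] result
#' @param rlbwt the matching [run_length_encode()] result
#' @param i,j global run indices of an adjacent same-symbol run pair
#' @param t candidate threshold offset; must lie in `(tail_i, head_j]`
#' @return `TRUE` iff both conditions hold
#' @export
verify_threshold <- function(bundle, rlbwt, i, j, t) {
  runs <- rlbwt$runs
  stopifnot(i < j, runs$c[i] == runs$c[j])
  if (j > i + 1L && any(runs$c[(i + 1L):(j - 1L)] == runs$c[i])) {
    stop("runs ", i, " and ", j, " are not adjacent for their symbol")
  }
  tail_i <- runs$h[i] + runs$l[i] - 1L
  head_j <- runs$h[j]
  if (t <= tail_i || t > head_j) {
    stop("threshold ", t, " outside the legal interval (", tail_i, ", ",
         head_j, "]")
  }
  lcp <- bundle$lcp
  ks <- if (tail_i + 1L <= head_j - 1L) (tail_i + 1L):(head_j - 1L) else integer()
  if (!length(ks)) return(TRUE)
  # LCP(k, tail_i) = min lcp[(tail_i+1)..k]; LCP(k, head_j) = min lcp[(k+1)..head_j]
  lcp_up <- cummin(lcp[ks])
  lcp_down <- rev(cummin(rev(lcp[(tail_i + 2L):head_j])))
  above <- ks < t
  all(lcp_up[above] >= lcp_down[above]) && all(lcp_up[!above] <= lcp_down[!above])
}

#' Map global thresholds onto a row partition as row-relative offsets
#'
#' For a row with head `h`, length `l`, and mismatch symbol `y` whose
#' governing adjacent pair has threshold `t`, the stored value is
#' `clamp(t - h, 0, l)`. Rows lexicographically before the first `y`-run store
#' 0 (always reposition down); rows after the last `y`-run store `l` (always
#' up). A relative value strictly inside `(0, l)` is a non-trivial threshold.
#'
#' @param ts a [compute_thresholds()] result
#' @param rows data.frame with columns `c`, `h`, `l` partitioning the BWT
#'   (maximal runs or any splitting of them)
#' @return integer matrix `nrow(rows) x 4` (columns A,C,G,T) of row-relative
#'   threshold offsets; `NA` in the column matching the row's own symbol.
#' @export
map_thresholds_to_rows <- function(ts, rows) {
  if (any(rows$h != cumsum(c(1L, rows$l[-nrow(rows)]))) || any(rows$l < 1L)) {
    stop("row set does not partition the BWT")
  }
  out <- matrix(0L, nrow = nrow(rows), ncol = SIGMA,
                dimnames = list(NULL, ALPHABET))
  for (y in seq_len(SIGMA)) {
    p <- ts$pairs[[y]]
    yr <- ts$runs_by_symbol[[y]]
    K <- nrow(yr)
    rel <- integer(nrow(rows))
    if (K >= 1L) {
      # g = number of maximal y-run tails at or before the row head: 0 means
      # before the first y-run (store 0, always down); K means after the last
      # y-run (store l, always up); otherwise pair g governs the gap
      g <- findInterval(rows$h, yr$tail)
      rel[g == K] <- rows$l[g == K]
      mid <- g >= 1L & g < K
      k <- g[mid]
      rel[mid] <- pmax(0L, pmin(rows$l[mid], p$t[k] - rows$h[mid]))
    }
    # symbol absent from the text: leave 0 (never consulted; reposition
    # refuses absent symbols upstream)
    out[, y] <- rel
    out[rows$c == y, y] <- NA_integer_
  }
  out
}
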