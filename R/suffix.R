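# Suffix array, BWT, LCP and the brute-force LF oracles.
#
# Conventions: text and BWT offsets are 1-based throughout, matching the
# standard presentation of the BWT literature. The sentinel has code 0 and is
# the unique smallest symbol, so the suffix starting at the sentinel is always
# the lexicographically smallest.

# Prefix-doubling suffix array over small integer codes. O(n log n) with
# radix-based order(); correctness (not speed) is the contract, and the naive
# string-sort oracle in the test suite cross-checks it.
suffix_array_codes <- function(codes) {
  n <- length(codes)
  if (n == 1L) return(1L)
  rank <- codes + 1L
  k <- 1L
  repeat {
    rank2 <- c(rank[-seq_len(min(k, n))], integer(min(k, n)))
    o <- order(rank, rank2, method = "radix")
    r1 <- rank[o]
    r2 <- rank2[o]
    changed <- c(TRUE, r1[-1L] != r1[-n] | r2[-1L] != r2[-n])
    newr <- cumsum(changed)
    rank[o] <- newr
    if (newr[n] == n) break
    k <- k * 2L
  }
  order(rank, method = "radix")
}

# Kasai's algorithm: lcp[j] = LCP of sorted suffixes j-1 and j, lcp[1] = 0.
# Amortised O(n) even as an interpreted loop: h rises at most n times overall.
lcp_kasai <- function(codes, sa) {
  n <- length(codes)
  rank <- integer(n)
  rank[sa] <- seq_len(n)
  lcp <- integer(n)
  h <- 0L
  for (i in seq_len(n)) {
    ri <- rank[i]
    if (ri > 1L) {
      j <- sa[ri - 1L]
      while (i + h <= n && j + h <= n && codes[i + h] == codes[j + h]) {
        h <- h + 1L
      }
      lcp[ri] <- h
      if (h > 0L) h <- h - 1L
    } else {
      h <- 0L
    }
  }
  lcp
}

#' Build the suffix bundle: suffix array, BWT, LCP array and symbol counts
#'
#' The bundle is the uncompressed ground truth every compressed component is
#' tested against. `sa` holds the 1-based start offsets of the suffixes in
#' lexicographic order; `bwt[j]` is the symbol preceding suffix `sa[j]`
#' (wrapping to the sentinel when `sa[j] == 1`); `lcp[j]` is the longest
#' common prefix length of the sorted suffixes `j-1` and `j` (`lcp[1] = 0`);
#' `c_counts[c]` is the number of text symbols lexicographically smaller than
#' symbol `c`.
#'
#' @param text a [pangenome_text()] object
#' @return an object of class `suffix_bundle` with fields `sa`, `bwt`, `lcp`,
#'   `c_counts` (named vector over `$`, A, C, G, T), `n`, and `text` (the
#'   input, retained for the oracles).
#' @examples
#' b <- build_suffix_bundle(text_from_string("ACACGT"))
#' paste(decode_symbols(b$bwt), collapse = "")  # "T$CAACG"
#' @export
build_suffix_bundle <- function(text) {
  stopifnot(inherits(text, "pangenome_text"))
  codes <- text$symbols
  n <- text$n
  sa <- suffix_array_codes(codes)
  prev <- sa - 1L
  prev[prev == 0L] <- n
  bwt <- codes[prev]
  lcp <- lcp_kasai(codes, sa)
  counts <- tabulate(codes + 1L, nbins = SIGMA + 1L)  # counts of $,A,C,G,T
  c_counts <- cumsum(c(0L, counts[-(SIGMA + 1L)]))
  names(c_counts) <- c("$", ALPHABET)
  structure(
    list(sa = sa, bwt = bwt, lcp = lcp, c_counts = c_counts, n = n, text = text),
    class = "suffix_bundle"
  )
}

#' @export
print.suffix_bundle <- function(x, ...) {
  cat(sprintf("suffix_bundle: n = %d, runs = %d\n", x$n,
              sum(x$bwt != c(x$bwt[-1L], -1L))))
  invisible(x)
}

#' Count occurrences of a symbol in a BWT prefix
#'
#' `bwt_rank(bundle, c, i)` is the number of occurrences of symbol `c` in
#' `L[1..i]`; `i = 0` returns 0.
#'
#' @param bundle a [build_suffix_bundle()] result
#' @param c symbol code (0 sentinel, 1..4 for A,C,G,T) or single character
#' @param i BWT offset in `0..n`
#' @return integer count
#' @export
bwt_rank <- function(bundle, c, i) {
  c <- as_symbol_code(c)
  stopifnot(i >= 0L, i <= bundle$n)
  if (i == 0L) return(0L)
  sum(bundle$bwt[seq_len(i)] == c)
}

# accept either an integer code or a single character
as_symbol_code <- function(c) {
  if (is.character(c)) {
    code <- if (c == "$") 0L else encode_symbols(toupper(c))
    if (is.na(code)) stop("unknown symbol: ", c)
    return(code)
  }
  as.integer(c)
}

#' LF-mapping computed directly from the suffix bundle (brute-force oracle)
#'
#' `LF(i) = C(L[i]) + rank_{L[i]}(i, L)`: the BWT offset of the same text
#' character in the first column of the sorted-rotation matrix. The sentinel's
#' position always maps to offset 1.
#'
#' @inheritParams bwt_rank
#' @param i BWT offset in `1..n`
#' @return BWT offset in `1..n`
#' @export
lf_direct <- function(bundle, i) {
  stopifnot(i >= 1L, i <= bundle$n)
  c <- bundle$bwt[i]
  bundle$c_counts[[c + 1L]] + bwt_rank(bundle, c, i)
}

# vectorised LF over all offsets at once; used by verification sweeps
lf_direct_all <- function(bundle) {
  bwt <- bundle$bwt
  n <- bundle$n
  lf <- integer(n)
  for (c in 0:SIGMA) {
    idx <- which(bwt == c)
    if (length(idx)) lf[idx] <- bundle$c_counts[[c + 1L]] + seq_along(idx)
  }
  lf
}

#' Run-length encode the BWT
#'
#' @param bundle a [build_suffix_bundle()] result
#' @return an object of class `rlbwt`: a list with `runs` (data.frame with
#'   columns `c` symbol code, `h` head offset, `l` length; tail is
#'   `h + l - 1`) and `r` (run count).
#' @examples
#' rl <- run_length_encode(build_suffix_bundle(text_from_string("ACACGT")))
#' rl$r  # 6
#' @export
run_length_encode <- function(bundle) {
  bwt <- bundle$bwt
  n <- bundle$n
  head_mask <- c(TRUE, bwt[-1L] != bwt[-n])
  h <- which(head_mask)
  l <- diff(c(h, n + 1L))
  runs <- data.frame(c = bwt[h], h = h, l = l)
  structure(list(runs = runs, r = nrow(runs)), class = "rlbwt")
}

#' @export
print.rlbwt <- function(x, ...) {
  cat(sprintf("rlbwt: r = %d runs over n = %d\n", x$r, sum(x$runs$l)))
  invisible(x)
}

#' Reconstruct the text by iterated LF-mapping from the sentinel's row
#'
#' Walks the LF permutation `n` steps starting at BWT offset 1 (the row whose
#' first-column symbol is the sentinel), reading characters right to left.
#' A cycle shorter than `n` signals a corrupt bundle.
#'
#' @param bundle a [build_suffix_bundle()] result
#' @return a `pangenome_text`-compatible integer code vector ending in the
#'   sentinel, identical to `bundle$text$symbols` for a valid bundle
#' @export
reconstruct_text <- function(bundle) {
  n <- bundle$n
  lf <- lf_direct_all(bundle)
  out <- integer(n)
  # L[1] is the last text character (precedes the sentinel suffix); walking
  # LF from offset 1 emits T[n-1], T[n-2], ..., T[1], then the sentinel.
  i <- 1L
  for (k in seq_len(n - 1L)) {
    out[n - k] <- bundle$bwt[i]
    i <- lf[i]
    if (i == 1L && k < n - 1L) stop("LF cycle shorter than n: corrupt bundle")
  }
  out[n] <- SENTINEL_CODE
  out
}
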