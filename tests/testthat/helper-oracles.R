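# Brute-force oracles, independent of the package's own algorithms, plus
# small fixture generators. Everything is locale-independent (integer code
# comparisons, never string collation).

# naive O(n^2 log n) suffix sort: order suffixes column by column on their
# padded code matrix (-1 pads past the end, below the sentinel's 0)
naive_suffix_array <- function(codes) {
  n <- length(codes)
  cols <- lapply(seq_len(n), function(j) {
    idx <- seq_len(n) + j - 1L
    out <- rep(-1L, n)
    ok <- idx <= n
    out[ok] <- codes[idx[ok]]
    out
  })
  do.call(order, cols)
}

naive_bwt <- function(codes, sa = naive_suffix_array(codes)) {
  prev <- sa - 1L
  prev[prev == 0L] <- length(codes)
  codes[prev]
}

# direct pairwise LCP of adjacent sorted suffixes
naive_lcp <- function(codes, sa = naive_suffix_array(codes)) {
  n <- length(codes)
  lcp <- integer(n)
  for (j in seq_len(n)[-1L]) {
    a <- sa[j - 1L]
    b <- sa[j]
    h <- 0L
    while (a + h <= n && b + h <= n && codes[a + h] == codes[b + h]) h <- h + 1L
    lcp[j] <- h
  }
  lcp
}

# LF by counting occurrences, straight from the definition
naive_lf <- function(bwt, i) {
  c <- bwt[i]
  smaller <- sum(bwt < c)
  smaller + sum(bwt[seq_len(i)] == c)
}

# seeded random DNA string (skewed composition gives realistic run structure)
random_dna <- function(seed, n, prob = c(.3, .3, .2, .2)) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# step-by-step PML oracle on global BWT offsets: uses only the suffix
# bundle, the maximal-run partition and the global thresholds -- no move
# table, no splitting, no id compression, no serialization
pml_oracle <- function(text, pattern) {
  bundle <- build_suffix_bundle(text)
  rl <- run_length_encode(bundle)
  ts <- compute_thresholds(bundle, rl)
  codes <- if (is.character(pattern)) {
    ch <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
    co <- match(ch, c("A", "C", "G", "T"))
    co[is.na(co)] <- 1L
    co
  } else as.integer(pattern)
  n <- bundle$n
  bwt <- bundle$bwt
  lf <- vapply(seq_len(n), function(i) naive_lf(bwt, i), 0L)
  runs <- rl$runs
  run_info <- lapply(1:4, function(y) {
    idx <- which(runs$c == y)
    list(h = runs$h[idx], t = runs$h[idx] + runs$l[idx] - 1L)
  })
  present <- vapply(1:4, function(y) any(bwt == y), TRUE)
  sentinel_off <- which(bwt == 0L)
  m <- length(codes)
  pml <- integer(m)
  g <- n
  for (k in seq.int(m, 1L)) {
    ck <- codes[k]
    if (bwt[g] == ck) {
      if (k < m) pml[k] <- pml[k + 1L] + 1L
      g <- lf[g]
    } else {
      if (k < m) pml[k] <- 0L
      if (present[ck]) {
        yr <- run_info[[ck]]
        K <- length(yr$h)
        gi <- findInterval(g, yr$t)
        dirup <- if (gi == 0L) FALSE
        else if (gi == K) TRUE
        else g < ts$pairs[[ck]]$t[gi]
        if (g == sentinel_off && ck == 1L) dirup <- !any(yr$h > g)
        g <- if (dirup) yr$t[gi] else yr$h[gi + 1L]
        g <- lf[g]
      }
    }
  }
  pml
}

# uncompressed destination ids for every row of a table built with any
# variant: recomputed from the LF oracle on row heads
uncompressed_ids <- function(table, text) {
  bundle <- build_suffix_bundle(text)
  pi <- vapply(table$rows$h, function(h) lf_direct(bundle, h), 0L)
  findInterval(pi, table$rows$h)
}

make_tiny <- function() text_from_string("ACACGT")
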