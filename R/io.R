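# Bit-exact index serialization.
#
# Single self-describing container file: a fixed header, then the bit-packed
# row array, then the checkpoint table (blocked/sampled variants). Row
# records are little-endian fixed-width bitfields, least-significant field
# first:
#   default  64 bits: c:2, l:11, f:11, xi:36, thr:3, spare:1   (8 bytes/row)
#   blocked  48 bits: c:2, l:10, f:10, delta:23, thr:3         (6 bytes/row)
#   sampled  24 bits: c:2, l:9,  f:9,  thr:3, spare:1          (3 bytes/row)
# Checkpoint ids are 40 bits each, 4 per checkpoint (20 bytes). Ids are
# stored 1-based so 0 can mark an empty checkpoint.

INDEX_MAGIC <- charToRaw("MV2I")
INDEX_VERSION <- 1L
VARIANT_CODES <- c(default = 0L, blocked = 1L, sampled = 2L)

row_field_widths <- function(variant, length_bits) {
  switch(variant,
    default = c(c = 2L, l = length_bits, f = length_bits, id = 36L,
                thr = 3L, spare = 1L),
    blocked = c(c = 2L, l = length_bits, f = length_bits, id = 23L, thr = 3L),
    sampled = c(c = 2L, l = length_bits, f = length_bits, thr = 3L, spare = 1L))
}

# pack records of fixed-width little-endian bitfields; fields is a list of
# equal-length numeric vectors, widths the per-field bit widths (total
# divisible by 8); returns a raw vector of sum(widths)/8 bytes per record
pack_bits_le <- function(fields, widths) {
  stopifnot(length(fields) == length(widths), sum(widths) %% 8L == 0L)
  nrec <- length(fields[[1L]])
  total <- sum(widths)
  bits <- matrix(0L, nrow = total, ncol = nrec)
  pos <- 0L
  for (k in seq_along(fields)) {
    x <- as.numeric(fields[[k]])
    if (any(x < 0 | x >= 2^widths[k])) {
      bad <- which(x < 0 | x >= 2^widths[k])[1L]
      stop("field ", names(widths)[k], " exceeds its ", widths[k],
           "-bit width at record ", bad)
    }
    for (b in seq_len(widths[k])) {
      bits[pos + b, ] <- x %% 2
      x <- x %/% 2
    }
    pos <- pos + widths[k]
  }
  packBits(as.integer(bits), type = "raw")
}

unpack_bits_le <- function(bytes, widths, nrec) {
  total <- sum(widths)
  bits <- matrix(as.integer(rawToBits(bytes)), nrow = total, ncol = nrec)
  out <- vector("list", length(widths))
  names(out) <- names(widths)
  pos <- 0L
  for (k in seq_along(widths)) {
    w <- widths[k]
    out[[k]] <- as.vector(2^(0:(w - 1L)) %*% bits[pos + seq_len(w), , drop = FALSE])
    pos <- pos + w
  }
  out
}

# three trivialised threshold bits for each row: mismatch symbols in
# ascending order relative to the row's symbol-as-stored (terminator stores
# symbol code A, so its bits cover C,G,T); bit 1 = up (threshold at l)
# a mismatch symbol y sits at bit position y - 1 - (stored_c < y) among the
# three symbols other than the row's stored symbol, in ascending order
thr_bits3 <- function(table) {
  rc <- table$row_count
  stored_c <- table$rows$c
  stored_c[table$terminator_row] <- 1L
  l <- table$rows$l
  bits <- integer(rc)
  for (y in seq_len(SIGMA)) {
    m <- stored_c != y
    v <- table$thr[, y]
    bad <- m & (is.na(v) | (v != 0L & v != l))
    if (any(bad)) {
      stop("non-trivial threshold at row ", which(bad)[1L],
           ": build with do_threshold_split = TRUE before serializing")
    }
    p <- y - 1L - (stored_c < y)
    bits[m] <- bits[m] + (v[m] == l[m]) * 2L^p[m]
  }
  bits
}

#' Serialize a move table to a single index file
#'
#' @param table a move table built with thresholds-splitting and a finite
#'   `length_bits`
#' @param path output file
#' @return invisibly `path`
#' @export
serialize_index <- function(table, path) {
  stopifnot(inherits(table, "move_table"))
  if (is.na(table$layout$length_bits)) {
    stop("tables built with length_bits = Inf cannot be serialized")
  }
  widths <- row_field_widths(table$variant, table$layout$length_bits)
  fields <- list(
    c = ifelse(seq_len(table$row_count) == table$terminator_row,
               0L, table$rows$c - 1L),
    l = table$rows$l,
    f = table$rows$f,
    id = switch(table$variant,
                default = table$rows$xi,
                blocked = table$rows$delta,
                sampled = NULL),
    thr = thr_bits3(table),
    spare = if (table$variant != "blocked") integer(table$row_count) else NULL
  )
  fields <- Filter(Negate(is.null), fields)
  row_bytes <- pack_bits_le(fields, widths)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(INDEX_MAGIC, con)
  ints <- c(version = INDEX_VERSION,
            variant = VARIANT_CODES[[table$variant]])
  writeBin(as.integer(ints), con, size = 4L, endian = "little")
  writeBin(as.double(table$n), con, size = 8L, endian = "little")
  param <- switch(table$variant, default = 0L,
                  blocked = table$block_size, sampled = table$sample_rate)
  nck <- if (is.null(table$checkpoints)) 0L else nrow(table$checkpoints)
  ints2 <- c(table$r_original, table$row_count, table$layout$length_bits,
             table$layout$id_bits, table$layout$delta_bits, param,
             table$terminator_row, nck, table$substitutions)
  writeBin(as.integer(ints2), con, size = 4L, endian = "little")
  writeBin(row_bytes, con)
  if (nck > 0L) {
    ck <- table$checkpoints
    ck_bytes <- pack_bits_le(lapply(seq_len(SIGMA), function(y) ck[, y]),
                             stats::setNames(rep(40L, SIGMA), ALPHABET))
    writeBin(ck_bytes, con)
  }
  invisible(path)
}

#' Load a move table from an index file
#'
#' Validates magic, version and sizes; the loaded table answers every query
#' identically to the serialized one and re-serializes byte-identically.
#'
#' @param path index file written by [serialize_index()]
#' @return a `move_table`
#' @export
deserialize_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) < 4L || !identical(magic, INDEX_MAGIC)) {
    stop("not a move-structure index (bad magic)")
  }
  ints <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  if (length(ints) < 2L) stop("truncated index header")
  if (ints[1L] != INDEX_VERSION) stop("unsupported index version: ", ints[1L])
  variant <- names(VARIANT_CODES)[match(ints[2L], VARIANT_CODES)]
  if (is.na(variant)) stop("unknown variant code: ", ints[2L])
  n <- readBin(con, "double", n = 1L, size = 8L, endian = "little")
  ints2 <- readBin(con, "integer", n = 9L, size = 4L, endian = "little")
  if (length(n) < 1L || length(ints2) < 9L) stop("truncated index header")
  r_original <- ints2[1L]; row_count <- ints2[2L]; length_bits <- ints2[3L]
  id_bits <- ints2[4L]; delta_bits <- ints2[5L]; param <- ints2[6L]
  terminator_row <- ints2[7L]; nck <- ints2[8L]; substitutions <- ints2[9L]
  if (row_count < 1L || terminator_row < 1L || terminator_row > row_count) {
    stop("corrupt index header (row counts out of range)")
  }
  widths <- row_field_widths(variant, length_bits)
  nbytes <- row_count * sum(widths) %/% 8L
  row_bytes <- readBin(con, "raw", n = nbytes)
  if (length(row_bytes) < nbytes) stop("truncated row array")
  fields <- unpack_bits_le(row_bytes, widths, row_count)

  l <- as.integer(fields$l)
  cc <- as.integer(fields$c) + 1L
  cc[terminator_row] <- SENTINEL_CODE
  rows <- data.frame(c = cc, h = cumsum(c(1L, l[-row_count])), l = l,
                     f = as.integer(fields$f))
  thr <- matrix(NA_integer_, nrow = row_count, ncol = SIGMA,
                dimnames = list(NULL, ALPHABET))
  stored_c <- as.integer(fields$c) + 1L
  bits <- as.integer(fields$thr)
  for (y in seq_len(SIGMA)) {
    m <- stored_c != y
    p <- y - 1L - (stored_c < y)
    bit <- (bits %/% 2L^p) %% 2L
    thr[m, y] <- ifelse(bit[m] == 1L, l[m], 0L)
  }
  tab <- structure(list(
    variant = variant, n = n, r_original = r_original, row_count = row_count,
    rows = rows, thr = thr, terminator_row = terminator_row,
    layout = list(length_bits = length_bits, id_bits = id_bits,
                  delta_bits = delta_bits, checkpoint_id_bytes = 5L),
    split_report = NULL,
    symbol_counts = stats::setNames(
      vapply(seq_len(SIGMA), function(y) sum(l[cc == y]), 0), ALPHABET),
    substitutions = substitutions
  ), class = "move_table")
  # reconstruct the sentinel row's A-direction by the build-time rule
  tab$thr[terminator_row, 1L] <- terminator_a_direction(rows, terminator_row)

  if (variant == "default") {
    tab$rows$xi <- as.integer(fields$id)
  } else if (variant == "blocked") {
    tab$rows$delta <- as.integer(fields$id)
    tab$block_size <- param
  } else {
    tab$sample_rate <- param
  }
  if (nck > 0L) {
    ck_bytes <- readBin(con, "raw", n = nck * 20L)
    if (length(ck_bytes) < nck * 20L) stop("truncated checkpoint table")
    ckf <- unpack_bits_le(ck_bytes, stats::setNames(rep(40L, SIGMA), ALPHABET), nck)
    tab$checkpoints <- matrix(as.integer(unlist(ckf)), nrow = nck,
                              dimnames = list(NULL, ALPHABET))
  }
  tab
}

#' Summary statistics of a move table
#'
#' @param table a move table
#' @return named list: counts, compression ratio `n/r`, splitting
#'   percentages (when the build-time report is available), bytes per row on
#'   disk, row-array and checkpoint-table sizes, and mean query-time work
#'   (fast-forward steps per LF, rows scanned per reposition and per
#'   sampled-id resolution) accumulated since the counters were last reset.
#' @export
index_stats <- function(table) {
  widths <- row_field_widths(table$variant, table$layout$length_bits)
  bits_per_row <- sum(widths)
  nck <- if (is.null(table$checkpoints)) 0L else nrow(table$checkpoints)
  row_bytes <- table$row_count * bits_per_row / 8
  ck_bytes <- nck * SIGMA * table$layout$checkpoint_id_bytes
  qc <- query_counters()
  out <- list(
    variant = table$variant,
    n = table$n,
    r_original = table$r_original,
    row_count = table$row_count,
    n_over_r = table$n / table$r_original,
    bits_per_row = bits_per_row,
    bytes_per_row = bits_per_row / 8,
    threshold_bits_per_row = unname(widths[["thr"]]),
    row_array_bytes = row_bytes,
    checkpoint_count = nck,
    checkpoint_table_bytes = ck_bytes,
    checkpoint_relative_pct = if (row_bytes > 0) 100 * ck_bytes / row_bytes else 0,
    mean_fast_forward = if (qc$lf_calls > 0) qc$ff_steps / qc$lf_calls else NA_real_,
    mean_reposition_scan = if (qc$repositions > 0)
      qc$reposition_rows / qc$repositions else NA_real_,
    mean_id_scan = if (qc$id_scans > 0) qc$id_scan_rows / qc$id_scans else NA_real_
  )
  if (!is.null(table$split_report)) {
    out$pct_threshold_split <- table$split_report$pct_threshold
    out$pct_length_split <- table$split_report$pct_length
  }
  out
}
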