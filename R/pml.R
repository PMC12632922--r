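# Pseudo Matching Length queries.
#
# PMLs lower-bound the matching statistics: PML[m] = 0 and, walking the
# pattern right to left with interleaved LF steps, PML[k] = PML[k+1] + 1 on a
# match of P[k] with the symbol at the current BWT position, and 0 on a
# mismatch, after which the position is repositioned (threshold-directed) to
# the nearest row of the mismatched symbol before the LF step. Because the
# reposition always lands on a row whose symbol is P[k], the following LF
# step is guaranteed to succeed.

#' Compute Pseudo Matching Lengths for one pattern
#'
#' Starts at the last BWT offset (last row, `v = l - 1`); `PML[m] = 0` by
#' definition (even when `P[m]` matches, the comparison still directs the
#' first movement). A symbol absent from the indexed text yields `PML[k] = 0`
#' with the position left unchanged.
#'
#' @param table a move table of any variant
#' @param pattern DNA string (character scalar) or integer code vector;
#'   non-ACGT characters are substituted with `"A"` deterministically,
#'   mirroring the indexing-side ambiguity policy
#' @param name pattern name carried into the result
#' @return an object of class `pml_result`: list with `name` and `pml`
#'   (integer vector of length `m`, left-to-right pattern order)
#' @examples
#' tab <- build_move_table(text_from_string("ACACGT"))
#' compute_pml(tab, "CA")$pml  # c(1, 0)
#' @export
compute_pml <- function(table, pattern, name = "pattern") {
  codes <- pattern_codes(pattern)
  m <- length(codes)
  stopifnot(m >= 1L)
  pml <- integer(m)
  pos <- bwt_position(table$row_count, table$rows$l[table$row_count] - 1L)
  present <- table$symbol_counts > 0
  for (k in seq.int(m, 1L)) {
    ck <- codes[k]
    if (char_at(table, pos) == ck) {
      if (k < m) pml[k] <- pml[k + 1L] + 1L
      pos <- move_lf(table, pos)
    } else {
      if (k < m) pml[k] <- 0L
      if (present[[ck]]) {
        pos <- reposition(table, pos, ck)
        pos <- move_lf(table, pos)
      }
      # absent symbol: PML is 0 and the position is left unchanged
    }
  }
  structure(list(name = name, pml = pml), class = "pml_result")
}

pattern_codes <- function(pattern) {
  if (is.character(pattern)) {
    chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
    codes <- encode_symbols(chars)
    codes[is.na(codes)] <- 1L  # deterministic ambiguity substitution
    codes
  } else {
    as.integer(pattern)
  }
}

#' @export
print.pml_result <- function(x, ...) {
  cat(">", x$name, "\n", paste(x$pml, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Brute-force matching statistics (oracle)
#'
#' `MS[k]` is the length of the longest prefix of `P[k..m]` that occurs as a
#' substring of the text (sentinel excluded). Quadratic-time reference
#' implementation used only to validate PMLs (`PML <= MS` positionwise).
#'
#' @param text a [pangenome_text()]
#' @param pattern DNA string or integer codes
#' @return integer vector of length `m`
#' @export
matching_statistics_naive <- function(text, pattern) {
  codes <- pattern_codes(pattern)
  m <- length(codes)
  tstr <- paste(decode_symbols(text$symbols[-text$n]), collapse = "")
  pstr <- paste(decode_symbols(codes), collapse = "")
  ms <- integer(m)
  # MS[k] <= MS[k+1] + 1, so test lengths downward from that bound
  for (k in seq.int(m, 1L)) {
    cap <- if (k == m) m - k + 1L else min(m - k + 1L, ms[k + 1L] + 1L)
    len <- 0L
    for (cand in seq.int(cap, 1L)) {
      if (grepl(substr(pstr, k, k + cand - 1L), tstr, fixed = TRUE)) {
        len <- cand
        break
      }
    }
    ms[k] <- len
  }
  ms
}

#' Compute PMLs for a stream of reads
#'
#' Order-preserving and per-read independent: results are identical whether
#' reads are queried one at a time or in a batch. Malformed records are
#' reported by name and skipped.
#'
#' @param table a move table
#' @param reads named character vector of read sequences, or a
#'   `DNAStringSet`/`QualityScaledDNAStringSet`
#' @return list of [compute_pml()] results, in input order
#' @export
compute_pml_batch <- function(table, reads) {
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  if (length(reads) == 0L) return(list())
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  out <- vector("list", length(reads))
  keep <- logical(length(reads))
  for (i in seq_along(reads)) {
    if (is.na(reads[[i]]) || !nzchar(reads[[i]])) {
      warning("skipping malformed read record: ", names(reads)[i])
      next
    }
    out[[i]] <- compute_pml(table, reads[[i]], name = names(reads)[i])
    keep[i] <- TRUE
  }
  out[keep]
}

#' Read query sequences from FASTA or FASTQ
#'
#' Format is chosen by extension (`.fq`/`.fastq`, optionally `.gz`, are
#' FASTQ; anything else FASTA); parsing is delegated to Biostrings.
#'
#' @param path reads file
#' @return named character vector of sequences
#' @export
read_queries <- function(path) {
  if (!file.exists(path)) stop("reads file not found: ", path)
  base <- sub("\\.gz$", "", path)
  fmt <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq" else "fasta"
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as.character(seqs)
}

#' Write PML results in the pseudo-lengths text format
#'
#' One record per read: a `>name` line followed by a line of space-separated
#' PML integers in left-to-right read order.
#'
#' @param results list of [compute_pml()] results
#' @param path output file; `""` writes to stdout
#' @return invisibly `path`
#' @export
write_pml <- function(results, path = "") {
  lines <- unlist(lapply(results, function(r) {
    c(paste0(">", r$name), paste(r$pml, collapse = " "))
  }))
  if (is.null(lines)) lines <- character()
  writeLines(lines, con = if (nzchar(path)) path else stdout())
  invisible(path)
}
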