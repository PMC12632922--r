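#' @importFrom methods is
NULL

# Internal symbol codes: 0 = terminal sentinel '$', 1..4 = A, C, G, T.
# The sentinel sorts before every DNA symbol, matching lexicographic order
# of the codes.
ALPHABET <- c("A", "C", "G", "T")
SENTINEL_CODE <- 0L
SIGMA <- 4L

#' Encode a DNA character vector as integer codes
#'
#' @param chars character vector of single characters (upper case)
#' @return integer codes, NA for non-ACGT characters
#' @export
encode_symbols <- function(chars) {
  match(chars, ALPHABET)
}

#' Decode integer codes back to characters (0 renders as "$")
#' @param codes integer symbol codes (0 sentinel, 1..4 A,C,G,T)
#' @return character vector
#' @export
decode_symbols <- function(codes) {
  out <- c("$", ALPHABET)[codes + 1L]
  out
}

#' Build a concatenated pangenome text from named DNA sequences
#'
#' Concatenates the input records in order and appends a single terminal
#' sentinel, which sorts before every DNA symbol. Record boundaries are
#' retained so downstream consumers can attribute offsets to records, but no
#' per-record separators are inserted: the alphabet stays at four symbols plus
#' one sentinel, which is what keeps the bit-packed row layouts at two bits
#' per symbol. Matches that straddle a record boundary are therefore possible
#' and are documented as a known artifact of this concatenation scheme.
#'
#' @param sequences named character vector (or [Biostrings::DNAStringSet]) of
#'   DNA sequences; case-insensitive.
#' @param policy how to handle non-ACGT symbols: `"substitute"` replaces each
#'   with `"A"` deterministically and counts the substitutions;
#'   `"error"` aborts on the first such symbol.
#' @return an object of class `pangenome_text`: a list with `symbols`
#'   (integer codes, terminated by the sentinel code 0), `n` (total length
#'   including the sentinel), `sigma` (4), `boundaries` (data.frame with
#'   `name`, `start`, `length`), and `substitutions` (count of replaced
#'   ambiguity symbols).
#' @examples
#' tx <- pangenome_text(c(chr1 = "ACG"))
#' tx$n  # 4: three bases plus the sentinel
#' @export
pangenome_text <- function(sequences, policy = c("substitute", "error")) {
  policy <- match.arg(policy)
  if (is(sequences, "DNAStringSet") || is(sequences, "XStringSet")) {
    sequences <- as.character(sequences)
  }
  if (length(sequences) == 0L) {
    stop("at least one input record is required")
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("record", seq_along(sequences))
  }
  if (any(!nzchar(sequences))) {
    stop("empty input record: ", names(sequences)[!nzchar(sequences)][1L])
  }
  lens <- nchar(sequences)
  chars <- strsplit(toupper(paste(sequences, collapse = "")), "", fixed = TRUE)[[1L]]
  codes <- encode_symbols(chars)
  n_bad <- sum(is.na(codes))
  if (n_bad > 0L) {
    if (policy == "error") {
      stop("non-ACGT symbol present (", n_bad, " total) and policy = \"error\"")
    }
    codes[is.na(codes)] <- 1L  # deterministic substitution with 'A'
  }
  symbols <- c(codes, SENTINEL_CODE)
  structure(
    list(
      symbols = symbols,
      n = length(symbols),
      sigma = SIGMA,
      boundaries = data.frame(
        name = names(sequences),
        start = cumsum(c(1L, lens[-length(lens)])),
        length = as.integer(lens),
        stringsAsFactors = FALSE
      ),
      substitutions = as.integer(n_bad)
    ),
    class = "pangenome_text"
  )
}

#' Read a multi-FASTA file into a pangenome text
#'
#' Standard FASTA parsing (multi-record, wrapped lines, case-insensitive,
#' gzip accepted) is delegated to [Biostrings::readDNAStringSet()].
#'
#' @param path path to a FASTA file (optionally gzip-compressed)
#' @inheritParams pangenome_text
#' @return a `pangenome_text` object; see [pangenome_text()].
#' @export
ingest_fasta <- function(path, policy = c("substitute", "error")) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  pangenome_text(seqs, policy = match.arg(policy))
}

#' @export
print.pangenome_text <- function(x, ...) {
  cat(sprintf(
    "pangenome_text: n = %d (incl. sentinel), %d record(s), %d ambiguity substitution(s)\n",
    x$n, nrow(x$boundaries), x$substitutions
  ))
  invisible(x)
}

#' Render a pangenome text as a plain string (sentinel as "$")
#' @param text a `pangenome_text`
#' @return single character string
#' @export
text_as_string <- function(text) {
  paste(decode_symbols(text$symbols), collapse = "")
}

#' Build a pangenome text from a plain string that may include a trailing "$"
#'
#' Convenience for tests and examples: `"ACACGT$"` and `"ACACGT"` produce the
#' same text.
#' @param s character scalar
#' @param name record name
#' @return a `pangenome_text`
#' @export
text_from_string <- function(s, name = "seq") {
  s <- sub("\\$$", "", s)
  x <- stats::setNames(s, name)
  pangenome_text(x)
}

# run-once seed sandboxing: evaluate expr under a fixed seed without
# disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
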