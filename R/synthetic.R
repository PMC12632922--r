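# Deterministic synthetic pangenomes, reads, and adversarial texts.
#
# The generator emulates the repetitiveness structure that makes run-length
# compressed indexes worthwhile: one random base genome plus closely-related
# haplotype copies, so total length n grows linearly with the number of
# haplotypes while the BWT run count r grows much more slowly. Indels are
# uniform short deletions/insertions; no attempt is made to model real
# variation spectra or sequencing error profiles.

#' Specification of a synthetic pangenome
#'
#' Defaults describe the regression fixture used throughout the package:
#' 20 haplotypes of a 50 kb base genome at 0.1% substitution divergence with
#' sparse short indels.
#'
#' @param base_length length of the random base genome
#' @param n_haplotypes total haplotype count (the base plus mutated copies)
#' @param substitution_rate per-base substitution probability per haplotype
#' @param indel_rate per-base probability of starting an indel
#' @param max_indel_len maximum indel length (uniform in `1..max_indel_len`)
#' @param seed mandatory RNG seed; generation is bit-reproducible per seed
#' @return a `pangenome_spec` list
#' @export
pangenome_spec <- function(base_length = 50000L, n_haplotypes = 20L,
                           substitution_rate = 0.001, indel_rate = 2e-4,
                           max_indel_len = 10L, seed) {
  stopifnot(!missing(seed),
            substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            base_length >= 1L, n_haplotypes >= 1L, max_indel_len >= 1L)
  structure(list(base_length = as.integer(base_length),
                 n_haplotypes = as.integer(n_haplotypes),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 max_indel_len = as.integer(max_indel_len),
                 seed = as.integer(seed)),
            class = "pangenome_spec")
}

mutate_haplotype <- function(base_chars, sub_rate, indel_rate, max_len) {
  n <- length(base_chars)
  chars <- base_chars
  if (sub_rate > 0) {
    idx <- which(stats::runif(n) < sub_rate)
    if (length(idx)) {
      shift <- sample.int(3L, length(idx), replace = TRUE)
      code <- match(chars[idx], ALPHABET)
      chars[idx] <- ALPHABET[((code - 1L + shift) %% 4L) + 1L]
    }
  }
  if (indel_rate > 0) {
    pieces <- as.list(chars)
    idx <- which(stats::runif(n) < indel_rate)
    for (i in idx) {
      len <- sample.int(max_len, 1L)
      if (stats::runif(1) < 0.5) {
        drop <- i:min(n, i + len - 1L)
        pieces[drop] <- list("")
      } else {
        ins <- paste(sample(ALPHABET, len, replace = TRUE), collapse = "")
        pieces[[i]] <- paste0(ins, chars[i])
      }
    }
    chars <- unlist(pieces)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic pangenome
#'
#' @param spec a [pangenome_spec()]
#' @param out optional FASTA path; when given, the sequences are also written
#'   (uncompressed, via Biostrings)
#' @return named character vector of haplotype sequences
#' @export
generate_pangenome <- function(spec, out = NULL) {
  stopifnot(inherits(spec, "pangenome_spec"))
  seqs <- with_seed(spec$seed, {
    base <- sample(ALPHABET, spec$base_length, replace = TRUE)
    haps <- character(spec$n_haplotypes)
    haps[1L] <- paste(base, collapse = "")
    if (spec$n_haplotypes > 1L) {
      for (k in 2:spec$n_haplotypes) {
        haps[k] <- mutate_haplotype(base, spec$substitution_rate,
                                    spec$indel_rate, spec$max_indel_len)
      }
    }
    stats::setNames(haps, sprintf("hap%02d", seq_len(spec$n_haplotypes)))
  })
  if (!is.null(out)) write_fasta(seqs, out)
  seqs
}

#' Write named sequences as FASTA
#' @param seqs named character vector
#' @param path output path
#' @return invisibly `path`
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

#' Simulate reads from a sequence collection
#'
#' Start positions are uniform over the concatenated source (records chosen
#' with probability proportional to the number of valid start positions);
#' substitution errors are applied per base at `error_rate`. Deterministic
#' per seed.
#'
#' @param seqs named character vector of source sequences (or a
#'   `pangenome_text`)
#' @param n_reads number of reads
#' @param read_length read length; must not exceed the longest record
#' @param error_rate per-base substitution error probability
#' @param seed mandatory RNG seed
#' @param out optional FASTQ path (constant quality "I")
#' @return named character vector of read sequences
#' @export
generate_reads <- function(seqs, n_reads, read_length, error_rate = 0,
                           seed, out = NULL) {
  stopifnot(!missing(seed), n_reads >= 0L, read_length >= 1L,
            error_rate >= 0, error_rate <= 1)
  if (inherits(seqs, "pangenome_text")) {
    seqs <- stats::setNames(sub("\\$$", "", text_as_string(seqs)), "text")
  }
  lens <- nchar(seqs)
  valid <- pmax(0L, lens - as.integer(read_length) + 1L)
  if (sum(valid) == 0L) stop("read_length exceeds every source record")
  reads <- with_seed(seed, {
    if (n_reads == 0L) return(stats::setNames(character(), character()))
    rec <- sample.int(length(seqs), n_reads, replace = TRUE, prob = valid)
    start <- vapply(rec, function(k) sample.int(valid[k], 1L), 0L)
    rd <- substr(rep(unname(seqs)[rec], 1L), start, start + read_length - 1L)
    if (error_rate > 0) {
      rd <- vapply(rd, function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        idx <- which(stats::runif(length(ch)) < error_rate)
        if (length(idx)) {
          shift <- sample.int(3L, length(idx), replace = TRUE)
          code <- match(ch[idx], ALPHABET)
          ch[idx] <- ALPHABET[((code - 1L + shift) %% 4L) + 1L]
        }
        paste(ch, collapse = "")
      }, character(1L), USE.NAMES = FALSE)
    }
    stats::setNames(rd, sprintf("read%05d", seq_len(n_reads)))
  })
  if (!is.null(out)) write_fastq(reads, out)
  reads
}

#' Write reads as FASTQ with constant quality
#' @param reads named character vector
#' @param path output path
#' @return invisibly `path`
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads), function(w) strrep("I", w), character(1L)))
  qx <- Biostrings::QualityScaledDNAStringSet(x, qual)
  Biostrings::writeXStringSet(qx, filepath = path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Adversarial texts exercising the splitting machinery
#'
#' * `long_run`: periodic text whose BWT contains runs longer than
#'   `2^11 - 1`, forcing length-splitting at every shipped bit width;
#' * `periodic`: `"AC"` repeated 512 times (runs of ~512, minimal r);
#' * `alternating`: a text whose BWT has no two equal adjacent symbols
#'   (r = n) and no non-trivial thresholds, so neither splitting stage adds
#'   rows at `length_bits = 11` (found by search over short seeded texts);
#' * `nontrivial_threshold`: a short text carrying a strictly interior
#'   threshold, so thresholds-splitting must add at least one row (found by
#'   the same search).
#'
#' @return named list of plain text strings (no sentinel)
#' @export
adversarial_fixtures <- function() {
  list(
    long_run = strrep("AC", 2500L),
    periodic = strrep("AC", 512L),
    alternating = "GTCA",
    nontrivial_threshold = "TGTGGATGAGATTGTTCAAC"
  )
}
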