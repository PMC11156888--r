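#' Reverse-complement DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()];
#' accepts and returns plain strings (alphabet ACGTN).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Hamming distance between equal-length strings
#'
#' @param a,b character vectors (recycled); elements compared pairwise must
#'   have equal length. N counts as a mismatch against any other base.
#' @return integer vector of mismatch counts.
#' @export
hamming <- function(a, b) {
  stopifnot(all(nchar(a) == nchar(b) | is.na(a) | is.na(b)))
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b, USE.NAMES = FALSE)
}

## split one string into a character vector of single bases
dna_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

## mismatch counts of one pattern slid over every start of every sequence:
## returns, for a single subject string, an integer vector over offsets
## 1..(nchar(subject)-nchar(pattern)+1). Pure Hamming, N never matches.
slide_mismatches <- function(subject, pattern) {
  n <- nchar(subject) - nchar(pattern) + 1L
  if (n < 1L) return(integer())
  sc <- dna_chars(subject)
  pc <- dna_chars(pattern)
  mm <- integer(n)
  for (j in seq_along(pc)) {
    mm <- mm + (sc[j:(j + n - 1L)] != pc[j])
  }
  mm
}

## IUPAC degenerate match: does base (ACGT) satisfy pattern char?
## Returns a logical matrix helper used by PAM scanning.
iupac_allows <- function(pattern_char, bases) {
  allowed <- dna_chars(Biostrings::IUPAC_CODE_MAP[[pattern_char]])
  bases %in% allowed
}

## uniform random DNA string(s)
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

## deterministic integer -> fixed-width DNA encoding (base-4), used to draw
## UMIs without replacement from the 4^len space
int_to_dna <- function(i, len) {
  bases <- c("A", "C", "G", "T")
  out <- character(length(i))
  for (k in seq_along(i)) {
    v <- i[k] - 1L
    digs <- integer(len)
    for (j in len:1) {
      digs[j] <- v %% 4L
      v <- v %/% 4L
    }
    out[k] <- paste(bases[digs + 1L], collapse = "")
  }
  out
}

## substitute sequencing errors at a per-base rate; vectorised over reads
apply_substitution_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- dna_chars(s)
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      for (i in which(hit)) {
        ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
      }
    }
    paste(ch, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
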