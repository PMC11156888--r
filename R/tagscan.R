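#' Define a dsODN tag
#'
#' The dsODN is the short blunt duplex captured into Cas9-induced breaks by
#' end joining; its sequence in a read marks a tag-genome junction.
#' Detection uses the junction-proximal `anchor_length` bases of the tag
#' (34-, 39- and 46-nt designs are all supported; any 20-60 nt sequence is
#' accepted).
#'
#' @param name tag name used in manifests and reports.
#' @param sequence tag sequence, 20-60 nt, alphabet ACGT.
#' @param anchor_length junction-proximal bases used for detection
#'   (default 12; must be >= 10 and <= tag length).
#' @return an object of class `dsodn_spec`.
#' @export
dsodn_spec <- function(name, sequence, anchor_length = 12L) {
  sequence <- toupper(sequence)
  stopifnot(
    nchar(sequence) >= 20L, nchar(sequence) <= 60L,
    grepl("^[ACGT]+$", sequence),
    anchor_length >= 10L, anchor_length <= nchar(sequence)
  )
  structure(
    list(name = name, sequence = sequence, anchor_length = as.integer(anchor_length)),
    class = "dsodn_spec"
  )
}

#' Locate the dsODN tag anchor in reads
#'
#' Scans each read for the tag's junction-proximal anchor (its first
#' `anchor_length` bases) and for the anchor's reverse complement, anywhere
#' in the read. The lowest-mismatch hit wins; ties prefer forward
#' orientation, then the smallest offset.
#'
#' @param seqs character vector of read sequences.
#' @param spec a [dsodn_spec()].
#' @param max_anchor_mm maximum Hamming mismatches in the anchor (default 1).
#' @param max_full_mm mismatch tolerance for the full-length flag
#'   (default 1).
#' @return a `data.table` with one row per input read: `found`,
#'   `orientation` (`"forward"`/`"reverse"`), `read_offset` (0-based anchor
#'   start), `matched_length` (tag bases covered by the read, extending from
#'   the anchor), `mismatches` (in the anchor), `full_length`.
#' @export
find_tag <- function(seqs, spec, max_anchor_mm = 1L, max_full_mm = 1L) {
  anchor <- substr(spec$sequence, 1L, spec$anchor_length)
  anchor_rc <- revcomp(anchor)
  tlen <- nchar(spec$sequence)
  al <- spec$anchor_length

  n <- length(seqs)
  out <- data.table(
    found = logical(n), orientation = NA_character_,
    read_offset = NA_integer_, matched_length = NA_integer_,
    mismatches = NA_integer_, full_length = FALSE
  )
  if (!n) return(out)
  full <- is_full_length(seqs, spec, max_mm = max_full_mm)
  for (i in seq_len(n)) {
    s <- seqs[i]
    L <- nchar(s)
    mm_f <- slide_mismatches(s, anchor)
    mm_r <- slide_mismatches(s, anchor_rc)
    best_f <- if (length(mm_f)) min(mm_f) else Inf
    best_r <- if (length(mm_r)) min(mm_r) else Inf
    if (min(best_f, best_r) > max_anchor_mm) next
    if (best_f <= best_r) { # forward wins ties
      off <- which.min(mm_f) - 1L
      ## tag extends rightward from its 5' anchor
      mlen <- min(tlen, L - off)
      out[i, `:=`(found = TRUE, orientation = "forward", read_offset = off,
                  matched_length = as.integer(mlen),
                  mismatches = as.integer(best_f), full_length = full[i])]
    } else {
      off <- which.min(mm_r) - 1L
      ## reverse-complemented tag ends at the anchor's right edge and
      ## extends leftward in read coordinates
      mlen <- min(tlen, off + al)
      out[i, `:=`(found = TRUE, orientation = "reverse", read_offset = off,
                  matched_length = as.integer(mlen),
                  mismatches = as.integer(best_r), full_length = full[i])]
    }
  }
  out
}

#' Test for a complete dsODN integration
#'
#' True iff the entire tag sequence, or its reverse complement, occurs
#' within the read at Hamming distance `max_mm` or less. This is the
#' full-length criterion used both in discovery reads and in amplicon
#' full-length-rate quantification.
#'
#' @param seqs character vector of read sequences.
#' @param spec a [dsodn_spec()].
#' @param max_mm mismatch tolerance (default 1, absorbing sequencing error).
#' @return logical vector.
#' @export
is_full_length <- function(seqs, spec, max_mm = 1L) {
  if (!length(seqs)) return(logical())
  subj <- Biostrings::DNAStringSet(seqs)
  fwd <- Biostrings::vcountPattern(spec$sequence, subj, max.mismatch = max_mm)
  rev <- Biostrings::vcountPattern(revcomp(spec$sequence), subj, max.mismatch = max_mm)
  fwd + rev > 0L
}

#' Split a tagged read at the tag-genome junction
#'
#' Returns the genomic portion of each tagged read together with a side
#' label. Under a forward-orientation hit, bases preceding the tag are
#' `left_of_tag`; under a reverse hit the label flips. The returned fragment
#' also records which of its ends (`tag_end`, in read coordinates) abuts the
#' tag, which later fixes the junction coordinate on the genome. When the
#' junction-proximal portion is shorter than `min_fragment_length` the
#' other side of the tag is used instead; reads with no usable side yield
#' no fragment.
#'
#' If a second non-overlapping anchor is present (tandem integration), the
#' read is trimmed at the outermost junction and flagged `tandem`; the
#' tag-internal portion is discarded.
#'
#' @param reads `data.table` with `read_id`, `seq1`, `umi` (from
#'   [extract_umi()]).
#' @param hits per-read tag hits from [find_tag()] (same row order).
#' @param spec the [dsodn_spec()] that produced `hits`.
#' @param min_fragment_length minimum genomic fragment to keep (default 25).
#' @return `data.table` of junction fragments: `read_id`, `umi`,
#'   `genomic_seq`, `side` (`left_of_tag`/`right_of_tag`), `tag_end`
#'   (`left`/`right` end of `genomic_seq` touching the tag), `tandem`.
#' @export
split_at_junction <- function(reads, hits, spec, min_fragment_length = 25L) {
  stopifnot(nrow(reads) == nrow(hits))
  tlen <- nchar(spec$sequence)
  al <- spec$anchor_length
  res <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    if (!hits$found[i]) next
    s <- reads$seq1[i]
    L <- nchar(s)
    ori <- hits$orientation[i]
    off <- hits$read_offset[i]
    ## the integrated tag may be truncated, so the tag boundaries are found
    ## by extending the actual match outward from the anchor, not by
    ## assuming the full tag length
    if (ori == "forward") {
      tag_from <- off                      # 0-based tag start in read
      e <- extend_tag_match(s, off + al + 1L, spec$sequence, al + 1L, +1L)
      tag_to <- off + al + e               # 0-based, exclusive
    } else {
      rc_tag <- revcomp(spec$sequence)     # anchor rc sits at its 3' end
      tag_to <- off + al
      e <- extend_tag_match(s, off, rc_tag, tlen - al, -1L)
      tag_from <- off - e
    }
    ## tandem detection: a second anchor beyond the first tag copy
    tandem <- detect_second_anchor(s, spec, ori, tag_from, tag_to)
    if (tandem) tag_to <- min(L, tag_to + tlen)  # trim at outermost junction

    pre <- substr(s, 1L, tag_from)
    post <- substring(s, tag_to + 1L)
    pre_side <- if (ori == "forward") "left_of_tag" else "right_of_tag"
    post_side <- if (ori == "forward") "right_of_tag" else "left_of_tag"
    if (nchar(pre) >= min_fragment_length) {
      res[[i]] <- data.table(
        read_id = reads$read_id[i], umi = reads$umi[i], genomic_seq = pre,
        side = pre_side, tag_end = "right", tandem = tandem
      )
    } else if (!tandem && nchar(post) >= min_fragment_length) {
      ## tandem-internal fragments between two tag copies are discarded
      res[[i]] <- data.table(
        read_id = reads$read_id[i], umi = reads$umi[i], genomic_seq = post,
        side = post_side, tag_end = "left", tandem = tandem
      )
    }
  }
  out <- rbindlist(res)
  if (!nrow(out)) {
    out <- data.table(read_id = character(), umi = character(),
                      genomic_seq = character(), side = character(),
                      tag_end = character(), tandem = logical())
  }
  out
}

## greedy ungapped extension of the tag match away from the anchor:
## compares read (1-based position `rpos`) with the tag pattern (1-based
## `ppos`), stepping by `dir`, tolerating one internal mismatch
## (sequencing error). Returns the extension length up to the last
## confirmed match, so a tolerated mismatch at the tag boundary never
## swallows a genomic base.
extend_tag_match <- function(s, rpos, pattern, ppos, dir) {
  L <- nchar(s)
  P <- nchar(pattern)
  e <- 0L
  mism <- 0L
  last_match <- 0L
  while (rpos >= 1L && rpos <= L && ppos >= 1L && ppos <= P) {
    if (substr(s, rpos, rpos) != substr(pattern, ppos, ppos)) {
      mism <- mism + 1L
      if (mism > 1L) break
    } else {
      last_match <- e + 1L
    }
    e <- e + 1L
    rpos <- rpos + dir
    ppos <- ppos + dir
  }
  last_match
}

## second tag copy directly downstream of the first (read orientation)?
detect_second_anchor <- function(s, spec, ori, tag_from, tag_to) {
  tlen <- nchar(spec$sequence)
  al <- spec$anchor_length
  anchor <- if (ori == "forward") substr(spec$sequence, 1L, al) else
    revcomp(substr(spec$sequence, 1L, al))
  region_from <- tag_to + 1L
  region_to <- min(nchar(s), tag_to + tlen)
  if (region_to - region_from + 1L < al) return(FALSE)
  region <- substr(s, region_from, region_to)
  any(slide_mismatches(region, anchor) <= 1L)
}
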