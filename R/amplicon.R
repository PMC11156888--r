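#' Define a targeted amplicon
#'
#' Amplicons of 200-280 bp are typical, spanning the cut site; any
#' 100-1000 bp reference is accepted. The `target_anchor` is a subsequence
#' (>= 15 nt) that identifies on-target reads and must occur exactly once
#' in the reference amplicon.
#'
#' @param site_name amplicon/site name.
#' @param reference_amplicon unedited reference sequence.
#' @param target_anchor read-selection subsequence.
#' @param dsodn the [dsodn_spec()] whose insertions are quantified.
#' @param cut_pos 0-based position of the Cas9 cut within the amplicon
#'   (used by the simulator; default midpoint).
#' @return an object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(site_name, reference_amplicon, target_anchor,
                          dsodn, cut_pos = NULL) {
  reference_amplicon <- toupper(reference_amplicon)
  target_anchor <- toupper(target_anchor)
  stopifnot(
    nchar(reference_amplicon) >= 100L, nchar(reference_amplicon) <= 1000L,
    nchar(target_anchor) >= 15L,
    inherits(dsodn, "dsodn_spec")
  )
  n_occ <- length(gregexpr(target_anchor, reference_amplicon, fixed = TRUE)[[1L]])
  if (!grepl(target_anchor, reference_amplicon, fixed = TRUE) || n_occ != 1L) {
    stop("target_anchor must occur exactly once in reference_amplicon")
  }
  ## assay-design sanity: an amplicon sharing near-identity with the tag
  ## makes unedited reads indistinguishable from edited ones
  if (any(has_insertion(reference_amplicon, dsodn))) {
    warning("reference_amplicon itself matches a dsODN block within the ",
            "detection tolerance; unedited reads will be misclassified")
  }
  structure(
    list(site_name = site_name, reference_amplicon = reference_amplicon,
         target_anchor = target_anchor, dsodn = dsodn,
         cut_pos = as.integer(cut_pos %||% (nchar(reference_amplicon) %/% 2L))),
    class = "amplicon_spec"
  )
}

#' Select on-target amplicon reads
#'
#' Keeps reads containing the target anchor (either strand) within
#' `max_anchor_mm` mismatches; everything else is off-amplicon.
#'
#' @param seqs character vector of read sequences.
#' @param spec an [amplicon_spec()].
#' @param max_anchor_mm anchor mismatch tolerance (default 1).
#' @return logical vector, `TRUE` for target-bearing reads.
#' @export
select_target_reads <- function(seqs, spec, max_anchor_mm = 1L) {
  if (!length(seqs)) return(logical())
  subj <- Biostrings::DNAStringSet(seqs)
  fwd <- Biostrings::vcountPattern(spec$target_anchor, subj,
                                   max.mismatch = max_anchor_mm)
  rev <- Biostrings::vcountPattern(revcomp(spec$target_anchor), subj,
                                   max.mismatch = max_anchor_mm)
  fwd + rev > 0L
}

#' Detect any dsODN-derived block in a read
#'
#' True iff some contiguous tag block of at least `min_fragment` bases
#' (either orientation) occurs in the read within `max_mm` mismatches —
#' the pattern-match criterion that splits edited from unedited reads. A
#' block of length exactly `min_fragment` suffices: any longer qualifying
#' block contains one.
#'
#' @param seqs character vector of read sequences.
#' @param dsodn a [dsodn_spec()].
#' @param min_fragment minimum tag block length (default 10).
#' @param max_mm mismatch tolerance (default 1).
#' @return logical vector.
#' @export
has_insertion <- function(seqs, dsodn, min_fragment = 10L, max_mm = 1L) {
  if (!length(seqs)) return(logical())
  subj <- Biostrings::DNAStringSet(seqs)
  tag <- dsodn$sequence
  n_win <- nchar(tag) - min_fragment + 1L
  found <- rep(FALSE, length(seqs))
  for (i in seq_len(n_win)) {
    blk <- substr(tag, i, i + min_fragment - 1L)
    found <- found |
      Biostrings::vcountPattern(blk, subj, max.mismatch = max_mm) > 0L |
      Biostrings::vcountPattern(revcomp(blk), subj, max.mismatch = max_mm) > 0L
    if (all(found)) break
  }
  found
}

#' Length-excess windows for single and double insertions
#'
#' The classification windows, keyed by dsODN length: a read exceeding the
#' reference by 29-49 bp (34-nt tag) or 34-54 bp (39-nt tag) carries a
#' single insertion; an excess of 64-84 bp (34-nt) or 69-89 bp (39-nt)
#' indicates a double insertion. Bounds are inclusive. Windows for other
#' tag lengths can be supplied explicitly to [classify_read()].
#'
#' @param dsodn_len tag length (34 or 39 for the built-in windows).
#' @return list with integer `single` and `double` `(lo, hi)` windows.
#' @export
insertion_windows <- function(dsodn_len) {
  built_in <- list(
    `34` = list(single = c(29L, 49L), double = c(64L, 84L)),
    `39` = list(single = c(34L, 54L), double = c(69L, 89L))
  )
  w <- built_in[[as.character(dsodn_len)]]
  if (is.null(w)) {
    stop("no built-in insertion windows for dsODN length ", dsodn_len,
         "; supply windows explicitly")
  }
  w
}

#' Classify an amplicon read by length excess
#'
#' Reads without any insertion are `unedited`. Insertion-bearing reads are
#' classified by `excess = read_len - ref_len`: inside the single-insertion
#' window -> `single_insert`; inside the double window -> `double_insert`;
#' any other excess -> `edited_other` (truncated or rearranged
#' integrations). The four classes are mutually exclusive and exhaustive.
#'
#' @param read_len,ref_len integer vectors (recycled) of read and reference
#'   lengths.
#' @param dsodn_len tag length selecting the built-in windows (ignored when
#'   `windows` is given).
#' @param insertion_present logical vector from [has_insertion()].
#' @param windows optional list as returned by [insertion_windows()].
#' @return character vector of classes.
#' @export
classify_read <- function(read_len, ref_len, dsodn_len, insertion_present,
                          windows = NULL) {
  stopifnot(all(ref_len > 0L))
  w <- windows %||% insertion_windows(dsodn_len)
  excess <- read_len - ref_len
  out <- rep("edited_other", length(excess))
  out[excess >= w$single[1L] & excess <= w$single[2L]] <- "single_insert"
  out[excess >= w$double[1L] & excess <= w$double[2L]] <- "double_insert"
  out[!insertion_present] <- "unedited"
  out
}

#' Merge an overlapping read pair into one spanning sequence
#'
#' Exact-overlap merging for 150 bp pairs over short amplicons: the longest
#' suffix of read 1 matching a prefix of the reverse-complemented read 2
#' with at least `min_overlap` bases and at most `max_mm` mismatches wins;
#' read 1 bases are kept in the overlap. Pairs with no qualifying overlap
#' return `NA`.
#'
#' @param seq1,seq2 mate sequences (read 2 in sequencing orientation).
#' @param min_overlap minimum overlap length (default 20).
#' @param max_mm mismatch tolerance in the overlap (default 2).
#' @return merged sequence or `NA_character_`.
#' @export
merge_read_pair <- function(seq1, seq2, min_overlap = 20L, max_mm = 2L) {
  s2 <- revcomp(seq2)
  l1 <- nchar(seq1); l2 <- nchar(s2)
  for (ov in min(l1, l2):min_overlap) {
    a <- substring(seq1, l1 - ov + 1L)
    b <- substr(s2, 1L, ov)
    if (hamming(a, b) <= max_mm) {
      return(paste0(seq1, substring(s2, ov + 1L)))
    }
  }
  NA_character_
}

#' Summarize dsODN insertion outcomes over an amplicon read pool
#'
#' The full quantification: select target-bearing reads, split
#' edited/unedited by tag detection, classify insertion-bearing reads by
#' length excess, and flag complete-oligo reads. The insertion frequency
#' sums only single- and double-insertion reads over all target reads; the
#' full-length rate divides complete-oligo reads by all insertion-bearing
#' reads (including truncated ones) and is `NA` (flagged) when no read has
#' an insertion.
#'
#' @param seqs character vector of (merged or spanning) read sequences.
#' @param spec an [amplicon_spec()].
#' @param max_anchor_mm target-anchor tolerance (default 1).
#' @param min_fragment,max_mm tag-detection parameters (see
#'   [has_insertion()]).
#' @param windows optional length windows (see [classify_read()]).
#' @return list of class `amplicon_summary`: `site_name`,
#'   `n_total_target_reads`, `n_off_amplicon`, per-class counts,
#'   `n_full_length`, `insertion_frequency`, `full_length_rate`,
#'   `full_length_defined`.
#' @export
summarize_amplicon <- function(seqs, spec, max_anchor_mm = 1L,
                               min_fragment = 10L, max_mm = 1L,
                               windows = NULL) {
  keep <- select_target_reads(seqs, spec, max_anchor_mm = max_anchor_mm)
  target <- seqs[keep]
  n_total <- length(target)
  if (!n_total) {
    return(structure(list(
      site_name = spec$site_name, n_total_target_reads = 0L,
      n_off_amplicon = sum(!keep), n_unedited = 0L, n_single_insert = 0L,
      n_double_insert = 0L, n_edited_other = 0L, n_full_length = 0L,
      insertion_frequency = NA_real_, full_length_rate = NA_real_,
      full_length_defined = FALSE
    ), class = "amplicon_summary"))
  }
  ins <- has_insertion(target, spec$dsodn, min_fragment = min_fragment,
                       max_mm = max_mm)
  cls <- classify_read(nchar(target), nchar(spec$reference_amplicon),
                       nchar(spec$dsodn$sequence), ins, windows = windows)
  full <- is_full_length(target, spec$dsodn, max_mm = max_mm) & ins
  n_ins <- sum(ins)
  n_single <- sum(cls == "single_insert")
  n_double <- sum(cls == "double_insert")
  structure(list(
    site_name = spec$site_name,
    n_total_target_reads = n_total,
    n_off_amplicon = sum(!keep),
    n_unedited = sum(cls == "unedited"),
    n_single_insert = n_single,
    n_double_insert = n_double,
    n_edited_other = sum(cls == "edited_other"),
    n_full_length = sum(full),
    insertion_frequency = (n_single + n_double) / n_total,
    full_length_rate = if (n_ins > 0L) sum(full) / n_ins else NA_real_,
    full_length_defined = n_ins > 0L
  ), class = "amplicon_summary")
}

#' @export
print.amplicon_summary <- function(x, ...) {
  cat(sprintf("Amplicon '%s': %d target reads (%d off-amplicon)\n",
              x$site_name, x$n_total_target_reads, x$n_off_amplicon))
  cat(sprintf("  unedited %d | single %d | double %d | other %d\n",
              x$n_unedited, x$n_single_insert, x$n_double_insert,
              x$n_edited_other))
  cat(sprintf("  insertion frequency: %s\n",
              format(x$insertion_frequency, digits = 4)))
  cat(sprintf("  full-length rate:    %s\n",
              if (x$full_length_defined) format(x$full_length_rate, digits = 4)
              else "undefined (no insertions)"))
  invisible(x)
}
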