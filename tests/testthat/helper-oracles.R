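## Independent oracles, deliberately naive and written against different
## code paths than the package implementation.

## exhaustive per-character protospacer+PAM scan with explicit tie-breaks
oracle_scan_target <- function(chrom, position, guide, flank = 25L,
                               max_mismatches = 7L) {
  plen <- nchar(guide$protospacer)
  pamlen <- nchar(guide$pam)
  F <- plen + pamlen
  pam_sets <- lapply(strsplit(guide$pam, "")[[1L]], function(p) {
    strsplit(Biostrings::IUPAC_CODE_MAP[[p]], "")[[1L]]
  })
  best <- NULL
  for (s in (position - flank):(position + flank)) {
    if (s < 0L || s + F > nchar(chrom)) next
    for (strand in c("+", "-")) {
      frame <- substr(chrom, s + 1L, s + F)
      if (strand == "-") frame <- revcomp(frame)
      mm <- 0L
      for (i in 1:plen) {
        if (substr(frame, i, i) != substr(guide$protospacer, i, i)) mm <- mm + 1L
      }
      for (i in 1:pamlen) {
        if (!(substr(frame, plen + i, plen + i) %in% pam_sets[[i]])) mm <- mm + 1L
      }
      if (mm > max_mismatches) next
      cut <- if (strand == "+") s + plen - guide$cut_offset else
        s + pamlen + guide$cut_offset
      cand <- list(start = s, strand = strand, mm = mm,
                   cut_dist = abs(cut - position), frame = frame)
      if (is.null(best)) {
        best <- cand
      } else {
        better <-
          cand$mm < best$mm ||
          (cand$mm == best$mm && cand$cut_dist < best$cut_dist) ||
          (cand$mm == best$mm && cand$cut_dist == best$cut_dist &&
             cand$strand == "+" && best$strand == "-") ||
          (cand$mm == best$mm && cand$cut_dist == best$cut_dist &&
             cand$strand == best$strand && cand$start < best$start)
        if (better) best <- cand
      }
    }
  }
  best
}

## full-genome Hamming scan via Biostrings pattern matching (C code path,
## independent of the package's seed-and-extend aligner)
oracle_align <- function(fragment, genome, max_mm = 3L) {
  g <- Biostrings::DNAString(genome)
  hits <- list()
  for (spec in list(list(q = fragment, strand = "+"),
                    list(q = revcomp(fragment), strand = "-"))) {
    m <- Biostrings::matchPattern(spec$q, g, max.mismatch = max_mm)
    for (i in seq_along(m)) {
      st <- BiocGenerics::start(m)[i] - 1L
      win <- substr(genome, st + 1L, st + nchar(fragment))
      mm <- sum(strsplit(win, "")[[1L]] != strsplit(spec$q, "")[[1L]])
      hits[[length(hits) + 1L]] <- list(start = st, strand = spec$strand,
                                        mm = mm)
    }
  }
  if (!length(hits)) return(list(found = FALSE, ambiguous = FALSE))
  mms <- vapply(hits, `[[`, numeric(1L), "mm")
  top <- hits[mms == min(mms)]
  if (length(top) > 1L) {
    return(list(found = TRUE, ambiguous = TRUE, mm = min(mms)))
  }
  list(found = TRUE, ambiguous = FALSE, start = top[[1L]]$start,
       strand = top[[1L]]$strand, mm = top[[1L]]$mm)
}

## compare one align_fragment() result with the oracle verdict
aligner_agrees <- function(impl, ora) {
  if (is.null(impl)) return(!ora$found)
  if (!impl$unique) return(ora$found && ora$ambiguous)
  ora$found && !ora$ambiguous &&
    impl$start == ora$start && impl$strand == ora$strand &&
    impl$mismatches == ora$mm
}
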