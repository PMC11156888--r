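#' Define a guide RNA target
#'
#' @param name guide name.
#' @param protospacer 20-nt genomic target sequence (ACGT).
#' @param pam PAM pattern 3' of the protospacer; IUPAC codes allowed,
#'   default `"NGG"` (SpCas9). Pattern-N positions never contribute
#'   mismatches.
#' @param cut_offset blunt-cut position, bases 5' of the PAM (default 3,
#'   standard SpCas9); used for simulation and scan tie-breaking only.
#' @return an object of class `guide_spec`.
#' @export
guide_spec <- function(name, protospacer, pam = "NGG", cut_offset = 3L) {
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  stopifnot(
    grepl("^[ACGT]+$", protospacer),
    grepl("^[ACGTN]+$", pam),
    cut_offset > 0L, cut_offset < nchar(protospacer)
  )
  structure(
    list(name = name, protospacer = protospacer, pam = pam,
         cut_offset = as.integer(cut_offset)),
    class = "guide_spec"
  )
}

#' Consolidate integration junctions into cleavage sites
#'
#' Single-linkage clustering along each contig: a junction within
#' `merge_window` bases of a cluster's current span joins that cluster.
#' Each cluster becomes one cleavage site positioned at the read-weighted
#' modal junction (ties to the leftmost). Molecules are deduplicated by
#' exact `(umi, junction_pos, side)` identity.
#'
#' @param junctions junction `data.table` (see [align_fragments()]).
#' @param merge_window clustering distance in bases (default 10).
#' @return `data.table` of sites: `seq_name`, `position`, `window_start`,
#'   `window_end`, `read_count`, `umi_count`, `side_left`, `side_right`.
#' @export
consolidate <- function(junctions, merge_window = 10L) {
  if (!nrow(junctions)) {
    return(data.table(seq_name = character(), position = integer(),
                      window_start = integer(), window_end = integer(),
                      read_count = integer(), umi_count = integer(),
                      side_left = integer(), side_right = integer()))
  }
  j <- copy(junctions)
  setorder(j, seq_name, junction_pos)
  j[, cluster := {
    cl <- integer(.N)
    cur <- 1L
    cl[1L] <- 1L
    span_max <- junction_pos[1L]
    if (.N > 1L) for (i in 2:.N) {
      if (junction_pos[i] - span_max > merge_window) cur <- cur + 1L
      cl[i] <- cur
      span_max <- max(span_max, junction_pos[i])
    }
    cl
  }, by = seq_name]

  j[, {
    tab <- table(junction_pos)
    modal <- as.integer(names(tab)[tab == max(tab)])
    list(
      position = min(modal),                     # leftmost modal junction
      window_start = min(junction_pos),
      window_end = max(junction_pos) + 1L,       # half-open
      read_count = .N,
      umi_count = uniqueN(paste(umi, junction_pos, side)),
      side_left = sum(side == "left_of_tag"),
      side_right = sum(side == "right_of_tag")
    )
  }, by = .(seq_name, cluster)][, cluster := NULL][]
}

## per-frame mismatch evaluation shared by scan_target: frames are given in
## protospacer orientation; returns count vector and, on demand, positions
frame_mismatch_counts <- function(frames, guide) {
  F <- nchar(guide$protospacer) + nchar(guide$pam)
  plen <- nchar(guide$protospacer)
  mat <- matrix(unlist(strsplit(frames, "", fixed = TRUE)), nrow = F)
  pc <- dna_chars(guide$protospacer)
  mm <- colSums(mat[seq_len(plen), , drop = FALSE] != pc)
  for (i in seq_len(nchar(guide$pam))) {
    pat <- substr(guide$pam, i, i)
    if (pat == "N") next
    mm <- mm + !iupac_allows(pat, mat[plen + i, ])
  }
  as.integer(mm)
}

frame_mismatch_positions <- function(frame, guide) {
  plen <- nchar(guide$protospacer)
  fc <- dna_chars(frame)
  pc <- dna_chars(guide$protospacer)
  pos <- which(fc[seq_len(plen)] != pc) - 1L
  for (i in seq_len(nchar(guide$pam))) {
    pat <- substr(guide$pam, i, i)
    if (pat != "N" && !iupac_allows(pat, fc[plen + i])) {
      pos <- c(pos, plen + i - 1L)
    }
  }
  as.integer(pos)
}

#' Scan a cleavage site for its best protospacer+PAM match
#'
#' Slides a frame of length `nchar(protospacer) + nchar(pam)` over both
#' strands of the window `[position - flank, position + flank]` around a
#' consolidated junction. A mismatch is a base differing from the
#' protospacer, or a PAM base violating the PAM pattern (pattern N matches
#' anything and contributes nothing), i.e. one combined Hamming budget over
#' target and PAM. Ties at the minimal count are broken by (a) smaller
#' distance between the frame's implied cut position (`cut_offset` bases 5'
#' of the PAM) and the site position, then (b) the + strand, then (c) the
#' leftmost frame.
#'
#' @param reference named character vector of contig sequences (or a
#'   `ref_index`).
#' @param seq_name,position site contig and 0-based position.
#' @param guide a [guide_spec()].
#' @param flank half-width of the scanned window (default 25).
#' @param max_mismatches combined budget; frames above it are rejected
#'   (default 7).
#' @return `NULL` when no frame qualifies, else a list: `matched_seq`
#'   (protospacer-orientation genomic sequence), `target_strand`,
#'   `mismatch_count`, `mismatch_positions` (0-based within the frame),
#'   `frame_start` (0-based genomic), `implied_cut`.
#' @export
scan_target <- function(reference, seq_name, position, guide,
                        flank = 25L, max_mismatches = 7L) {
  if (inherits(reference, "ref_index")) reference <- reference$seqs
  if (!seq_name %in% names(reference)) {
    stop("reference contig not found: ", seq_name)
  }
  chrom <- reference[[seq_name]]
  G <- nchar(chrom)
  F <- nchar(guide$protospacer) + nchar(guide$pam)
  plen <- nchar(guide$protospacer)
  pamlen <- nchar(guide$pam)

  starts <- (position - flank):(position + flank)
  starts <- starts[starts >= 0L & starts + F <= G]
  if (!length(starts)) return(NULL)

  windows <- substring(chrom, starts + 1L, starts + F)
  cand <- rbindlist(list(
    data.table(start = starts, strand = "+", frame = windows),
    data.table(start = starts, strand = "-", frame = revcomp(windows))
  ))
  cand[, mismatches := frame_mismatch_counts(frame, guide)]
  ## implied blunt-cut coordinate of each frame (insertion-point convention)
  cand[, implied_cut := ifelse(strand == "+",
                               start + plen - guide$cut_offset,
                               start + pamlen + guide$cut_offset)]
  cand <- cand[mismatches <= max_mismatches]
  if (!nrow(cand)) return(NULL)

  cand[, cut_dist := abs(implied_cut - position)]
  setorder(cand, mismatches, cut_dist, strand, start)  # "+" < "-" in C locale
  best <- cand[1L]
  list(
    matched_seq = best$frame,
    target_strand = best$strand,
    mismatch_count = best$mismatches,
    mismatch_positions = frame_mismatch_positions(best$frame, guide),
    frame_start = best$start,
    implied_cut = best$implied_cut
  )
}

#' Annotate consolidated sites as off-target (or on-target) calls
#'
#' Runs [scan_target()] on every site; sites with no frame within the
#' mismatch budget are dropped and counted. The on-target call is the site
#' whose matched frame covers the configured on-target coordinate with zero
#' mismatches; when no coordinate is configured, the zero-mismatch call
#' with the highest read support is taken. Calls supported by fewer than 10
#' reads carry `low_read_flag` (variable reproducibility at low depth)
#' rather than being dropped.
#'
#' @param sites site table from [consolidate()].
#' @param guide a [guide_spec()].
#' @param reference named character vector of contigs (or `ref_index`).
#' @param flank,max_mismatches passed to [scan_target()].
#' @param on_target optional list `(seq_name, position)` of the intended
#'   cut; a call within `flank` of it at 0 mismatches is the on-target.
#' @param low_read_threshold read support below which calls are flagged
#'   (default 10).
#' @return list with `calls` (a `data.table`) and `n_dropped`.
#' @export
call_sites <- function(sites, guide, reference, flank = 25L,
                       max_mismatches = 7L, on_target = NULL,
                       low_read_threshold = 10L) {
  res <- vector("list", nrow(sites))
  n_dropped <- 0L
  for (i in seq_len(nrow(sites))) {
    hit <- scan_target(reference, sites$seq_name[i], sites$position[i],
                       guide, flank = flank, max_mismatches = max_mismatches)
    if (is.null(hit)) { n_dropped <- n_dropped + 1L; next }
    res[[i]] <- data.table(
      seq_name = sites$seq_name[i], position = sites$position[i],
      window_start = sites$window_start[i], window_end = sites$window_end[i],
      read_count = sites$read_count[i], umi_count = sites$umi_count[i],
      side_left = sites$side_left[i], side_right = sites$side_right[i],
      matched_seq = hit$matched_seq, target_strand = hit$target_strand,
      mismatch_count = hit$mismatch_count,
      mismatch_positions = paste(hit$mismatch_positions, collapse = ","),
      frame_start = hit$frame_start, implied_cut = hit$implied_cut
    )
  }
  calls <- rbindlist(res)
  if (!nrow(calls)) {
    return(list(calls = empty_calls(), n_dropped = n_dropped))
  }
  calls[, low_read_flag := read_count < low_read_threshold]
  calls[, is_on_target := FALSE]
  if (!is.null(on_target)) {
    cand <- calls[, which(seq_name == on_target$seq_name &
                            mismatch_count == 0L &
                            abs(position - on_target$position) <= flank)]
  } else {
    cand <- calls[, which(mismatch_count == 0L)]
  }
  if (length(cand)) {
    ## highest-supported zero-mismatch call is the intended target
    cand <- cand[which.max(calls$read_count[cand])]
    calls[cand, is_on_target := TRUE]
  }
  setorder(calls, -read_count, seq_name, position)
  list(calls = calls, n_dropped = n_dropped)
}

empty_calls <- function() {
  data.table(
    seq_name = character(), position = integer(), window_start = integer(),
    window_end = integer(), read_count = integer(), umi_count = integer(),
    side_left = integer(), side_right = integer(), matched_seq = character(),
    target_strand = character(), mismatch_count = integer(),
    mismatch_positions = character(), frame_start = integer(),
    implied_cut = integer(), low_read_flag = logical(),
    is_on_target = logical()
  )
}

#' Classify call confidence across biological replicates
#'
#' Calls from different replicates are grouped into loci when they lie on
#' the same contig and target strand within `locus_tolerance` bases
#' (single linkage). A locus detected in at least `min_replicates`
#' replicates is high-confidence; loci seen in fewer are retained as
#' low-confidence, not discarded. The grouping is invariant to replicate
#' order.
#'
#' @param call_sets named list: one calls `data.table` (from
#'   [call_sites()]) per biological replicate.
#' @param min_replicates replicates required for high confidence
#'   (default 2).
#' @param locus_tolerance grouping distance in bases (default 10).
#' @return `data.table`: one row per locus with `seq_name`, `position`
#'   (median across replicates), `target_strand`, `n_replicates_detected`,
#'   `confidence` (`"high"`/`"low"`), and `read_counts`
#'   (`replicate:count` pairs, `;`-joined, in sorted replicate order).
#' @export
classify_confidence <- function(call_sets, min_replicates = 2L,
                                locus_tolerance = 10L) {
  stopifnot(length(call_sets) >= 1L)
  if (is.null(names(call_sets))) {
    names(call_sets) <- paste0("rep", seq_along(call_sets))
  }
  all <- rbindlist(lapply(names(call_sets), function(nm) {
    cs <- call_sets[[nm]]
    if (!nrow(cs)) return(NULL)
    data.table(replicate = nm, seq_name = cs$seq_name,
               position = cs$position, target_strand = cs$target_strand,
               read_count = cs$read_count)
  }))
  if (is.null(all) || !nrow(all)) {
    return(data.table(seq_name = character(), position = integer(),
                      target_strand = character(),
                      n_replicates_detected = integer(),
                      confidence = character(), read_counts = character()))
  }
  setorder(all, seq_name, target_strand, position, replicate)
  all[, locus_id := {
    cl <- integer(.N)
    cur <- 1L
    cl[1L] <- 1L
    span_max <- position[1L]
    if (.N > 1L) for (i in 2:.N) {
      if (position[i] - span_max > locus_tolerance) cur <- cur + 1L
      cl[i] <- cur
      span_max <- max(span_max, position[i])
    }
    cl
  }, by = .(seq_name, target_strand)]

  out <- all[, {
    reps <- sort(unique(replicate))
    per_rep <- vapply(reps, function(r) sum(read_count[replicate == r]),
                      numeric(1L))
    list(
      position = as.integer(stats::median(position)),
      n_replicates_detected = length(reps),
      read_counts = paste(sprintf("%s:%d", reps, as.integer(per_rep)),
                          collapse = ";")
    )
  }, by = .(seq_name, target_strand, locus_id)]
  out[, confidence := ifelse(n_replicates_detected >= min_replicates,
                             "high", "low")]
  setorder(out, seq_name, position)
  out[, .(seq_name, position, target_strand, n_replicates_detected,
          confidence, read_counts)]
}

#' Compute the off-index of a sample
#'
#' The off-index is the ratio of summed off-target read counts to the
#' on-target read count; larger values mean relatively more off-target
#' cleavage. Requires exactly one on-target call; with no off-target calls
#' the value is exactly 0.
#'
#' @param calls calls `data.table` from [call_sites()].
#' @return list: `off_reads_total`, `on_reads`, `value`; `value` is `NA`
#'   with an `explanation` when no on-target call is present.
#' @export
compute_off_index <- function(calls) {
  on <- calls[is_on_target == TRUE]
  if (nrow(on) != 1L) {
    return(list(off_reads_total = sum(calls[is_on_target == FALSE]$read_count),
                on_reads = NA_integer_, value = NA_real_,
                explanation = "off-index undefined: no unique on-target call"))
  }
  off <- sum(calls[is_on_target == FALSE]$read_count)
  list(off_reads_total = off, on_reads = on$read_count,
       value = off / on$read_count)
}

#' Render the mismatch-annotated site table
#'
#' Shows the on-target protospacer+PAM as a header and each call's matched
#' sequence with matching bases as `"."` and mismatched bases spelled out
#' (colorized in text/html output), alongside read counts, coordinates,
#' strand, mismatch count and (optionally) confidence. Rows are sorted by
#' read count descending, ties by coordinate.
#'
#' @param calls calls `data.table` from [call_sites()]; may carry a
#'   `confidence` column.
#' @param guide a [guide_spec()].
#' @param format `"tsv"`, `"text"` (ANSI color) or `"html"`.
#' @return character vector of output lines.
#' @export
render_site_table <- function(calls, guide, format = c("tsv", "text", "html")) {
  format <- match.arg(format)
  header_seq <- paste0(guide$protospacer, guide$pam)
  calls <- copy(calls)
  setorder(calls, -read_count, seq_name, position)

  dotted <- vapply(seq_len(nrow(calls)), function(i) {
    fc <- dna_chars(calls$matched_seq[i])
    mmpos <- calls$mismatch_positions[i]
    mm <- if (nzchar(mmpos)) as.integer(strsplit(mmpos, ",")[[1L]]) else integer()
    disp <- rep(".", length(fc))
    disp[mm + 1L] <- fc[mm + 1L]
    if (format == "text") {
      disp[mm + 1L] <- paste0("\033[31m", fc[mm + 1L], "\033[0m")
    } else if (format == "html") {
      disp[mm + 1L] <- sprintf("<span style=\"color:red\">%s</span>", fc[mm + 1L])
    }
    paste(disp, collapse = "")
  }, character(1L))

  conf <- if ("confidence" %in% names(calls)) calls$confidence else
    rep(NA_character_, nrow(calls))
  body <- data.table(
    sequence = dotted,
    contig = calls$seq_name,
    start = calls$position + 1L,            # 1-based for human-readable output
    strand = calls$target_strand,
    mismatches = calls$mismatch_count,
    reads = calls$read_count,
    umis = calls$umi_count,
    on_target = calls$is_on_target,
    confidence = conf
  )
  cols <- names(body)
  rows <- do.call(paste, c(lapply(body, as.character), sep = "\t"))
  head_row <- paste(c(header_seq, "contig", "start", "strand", "mismatches",
                      "reads", "umis", "on_target", "confidence"),
                    collapse = "\t")
  if (format == "html") {
    c("<table>",
      paste0("<tr><th>", gsub("\t", "</th><th>", head_row), "</th></tr>"),
      paste0("<tr><td>", gsub("\t", "</td><td>", rows), "</td></tr>"),
      "</table>")
  } else {
    c(head_row, rows)
  }
}
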