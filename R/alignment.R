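#' Build a k-mer seed index over a reference FASTA
#'
#' Exact-match seed table for the built-in ungapped aligner: every length-k
#' substring of every contig (N-free) is recorded at its 0-based offset on
#' the forward strand. Minus-strand occurrences are resolved at lookup time
#' by also querying the reverse complement of the query k-mer.
#'
#' @param fasta path to a reference FASTA file, or a named character vector
#'   of sequences.
#' @param k seed length (default 20).
#' @return a `ref_index` object: `$seqs` (named uppercase character vector)
#'   and a hashed k-mer seed table mapping each k-mer to its forward-strand
#'   occurrences.
#' @export
build_index <- function(fasta, k = 20L) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    if (!length(ss)) stop("empty FASTA: ", fasta)
    seqs <- setNames(toupper(as.character(ss)), sub("[ \t].*$", "", names(ss)))
  } else {
    seqs <- toupper(fasta)
    if (!length(seqs)) stop("empty reference")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate contig names in reference")

  ## occurrences are packed contig_index * 2^32 + offset into doubles (both
  ## factors far below the 2^53 exact-integer limit)
  all_kmers <- character()
  all_enc <- numeric()
  for (ci in seq_along(seqs)) {
    s <- seqs[[ci]]
    n <- nchar(s) - k + 1L
    if (n < 1L) next
    kmers <- substring(s, 1:n, k:(n + k - 1L))
    keep <- !grepl("N", kmers, fixed = TRUE)
    all_kmers <- c(all_kmers, kmers[keep])
    all_enc <- c(all_enc, ci * 2^32 + (0:(n - 1L))[keep])
  }
  seeds <- list2env(split(all_enc, all_kmers), hash = TRUE)
  structure(list(seqs = seqs, k = as.integer(k), seeds = seeds),
            class = "ref_index")
}

## decode packed occurrences into (contig index, offset)
decode_occ <- function(enc) {
  ci <- as.integer(enc %/% 2^32)
  list(contig = ci, offset = as.integer(enc - ci * 2^32))
}

#' Look up all genomic occurrences of a k-mer
#'
#' Returns exact occurrences on both strands: forward-strand rows match the
#' k-mer itself, minus-strand rows match its reverse complement.
#'
#' @param index a [build_index()] object.
#' @param kmer query of length `index$k`.
#' @return `data.table` with `seq_name`, `offset` (0-based), `strand`.
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(nchar(kmer) == index$k)
  res <- list()
  for (spec in list(list(km = kmer, strand = "+"),
                    list(km = revcomp(kmer), strand = "-"))) {
    enc <- get0(spec$km, envir = index$seeds, inherits = FALSE)
    if (is.null(enc)) next
    occ <- decode_occ(enc)
    res[[length(res) + 1L]] <- data.table(
      seq_name = names(index$seqs)[occ$contig],
      offset = occ$offset, strand = spec$strand
    )
  }
  if (!length(res)) {
    return(data.table(seq_name = character(), offset = integer(),
                      strand = character()))
  }
  rbindlist(res)
}

#' Align a junction fragment by exact seed and ungapped extension
#'
#' Seeds on the junction-proximal k-mer of the fragment (falling back to
#' further non-overlapping k-mers when the proximal seed finds nothing),
#' extends without gaps, and counts Hamming mismatches over the full
#' fragment on both strands. The best (fewest-mismatch) locus wins; two
#' distinct loci tying at the best count make the fragment ambiguous and it
#' is discarded (`unique = FALSE`).
#'
#' @param fragment fragment sequence (length >= `index$k`).
#' @param index a [build_index()] object.
#' @param max_mm maximum mismatches over the fragment (default 3).
#' @param tag_end which end of the fragment abuts the tag (`"left"` or
#'   `"right"`); used to pick the junction-proximal seed.
#' @return one-row `data.table` (`seq_name`, `start` 0-based, `strand`,
#'   `mismatches`, `unique`) or `NULL` when nothing aligns; a non-unique
#'   best hit returns a row with `unique = FALSE` and NA coordinates.
#' @export
align_fragment <- function(fragment, index, max_mm = 3L, tag_end = "right") {
  k <- index$k
  L <- nchar(fragment)
  if (L < k) return(NULL)

  ## seed offsets within the fragment, junction-proximal first
  seed_offs <- unique(c(
    if (tag_end == "right") L - k else 0L,
    seq(0L, L - k, by = k),
    L - k
  ))

  frag_rc <- revcomp(fragment)
  c_contig <- integer()
  c_start <- integer()
  c_strand <- character()
  for (so in seed_offs) {
    km <- substr(fragment, so + 1L, so + k)
    if (grepl("N", km, fixed = TRUE)) next
    enc <- get0(km, envir = index$seeds, inherits = FALSE)
    if (!is.null(enc)) {
      occ <- decode_occ(enc)
      c_contig <- c(c_contig, occ$contig)
      c_start <- c(c_start, occ$offset - so)
      c_strand <- c(c_strand, rep("+", length(occ$contig)))
    }
    enc <- get0(revcomp(km), envir = index$seeds, inherits = FALSE)
    if (!is.null(enc)) {
      occ <- decode_occ(enc)
      c_contig <- c(c_contig, occ$contig)
      c_start <- c(c_start, occ$offset - (L - k - so))
      c_strand <- c(c_strand, rep("-", length(occ$contig)))
    }
  }
  if (!length(c_start)) return(NULL)
  keep <- !duplicated(paste(c_contig, c_start, c_strand))
  c_contig <- c_contig[keep]; c_start <- c_start[keep]; c_strand <- c_strand[keep]

  fr_raw <- charToRaw(fragment)
  frr_raw <- charToRaw(frag_rc)
  mm <- rep(NA_integer_, length(c_start))
  for (i in seq_along(c_start)) {
    s <- c_start[i]
    ref <- index$seqs[[c_contig[i]]]
    if (s < 0L || s + L > nchar(ref)) next
    win <- charToRaw(substr(ref, s + 1L, s + L))
    q <- if (c_strand[i] == "+") fr_raw else frr_raw
    mm[i] <- sum(win != q)
  }
  ok <- which(!is.na(mm) & mm <= max_mm)
  if (!length(ok)) return(NULL)

  best <- min(mm[ok])
  top <- ok[mm[ok] == best]
  if (length(top) > 1L) {
    return(data.table(seq_name = NA_character_, start = NA_integer_,
                      strand = NA_character_, mismatches = as.integer(best),
                      unique = FALSE))
  }
  data.table(seq_name = names(index$seqs)[c_contig[top]],
             start = c_start[top], strand = c_strand[top],
             mismatches = as.integer(best), unique = TRUE)
}

#' Align a table of junction fragments and derive junction coordinates
#'
#' Runs [align_fragment()] over a fragment table from [split_at_junction()]
#' and converts each unique alignment into an integration junction: the
#' 0-based genomic coordinate of the insertion point adjacent to the tag,
#' with a genome-space side label.
#'
#' @param fragments `data.table` from [split_at_junction()].
#' @param index a [build_index()] object.
#' @param max_mm per-fragment mismatch cap (default 3).
#' @return list with `junctions` (`read_id`, `umi`, `seq_name`,
#'   `junction_pos`, `side`, `strand`) and counts `n_unaligned`,
#'   `n_ambiguous`.
#' @export
align_fragments <- function(fragments, index, max_mm = 3L) {
  res <- vector("list", nrow(fragments))
  n_unaligned <- 0L
  n_ambiguous <- 0L
  for (i in seq_len(nrow(fragments))) {
    hit <- align_fragment(fragments$genomic_seq[i], index, max_mm = max_mm,
                          tag_end = fragments$tag_end[i])
    if (is.null(hit)) { n_unaligned <- n_unaligned + 1L; next }
    if (!hit$unique) { n_ambiguous <- n_ambiguous + 1L; next }
    j <- junction_from_alignment(hit, nchar(fragments$genomic_seq[i]),
                                 fragments$tag_end[i])
    res[[i]] <- data.table(
      read_id = fragments$read_id[i], umi = fragments$umi[i],
      seq_name = hit$seq_name, junction_pos = j$pos, side = j$side,
      strand = hit$strand
    )
  }
  junctions <- rbindlist(res)
  if (!nrow(junctions)) {
    junctions <- data.table(read_id = character(), umi = character(),
                            seq_name = character(), junction_pos = integer(),
                            side = character(), strand = character())
  }
  list(junctions = junctions, n_unaligned = n_unaligned,
       n_ambiguous = n_ambiguous)
}

## junction coordinate: the 0-based insertion point adjacent to the tag.
## A fragment aligned at [s, s+L) whose read-space tag_end is "right"
## touches the tag at genomic s+L on the + strand, at s on the - strand;
## mirrored for tag_end "left". Side labels are genome-space.
junction_from_alignment <- function(hit, frag_len, tag_end) {
  s <- hit$start
  e <- s + frag_len
  if ((tag_end == "right") == (hit$strand == "+")) {
    list(pos = e, side = "left_of_tag")
  } else {
    list(pos = s, side = "right_of_tag")
  }
}

#' Ingest external alignments from a SAM file
#'
#' Alternative to the built-in aligner for production-scale genomes: reads
#' primary mapped records from a SAM file whose read names follow the
#' `readid|UMI|side|tag_end` convention (side in `left_of_tag`/
#' `right_of_tag`, tag_end in `left`/`right`, as written by
#' [write_fragments_fasta()]). Secondary/supplementary and unmapped records
#' are skipped and counted.
#'
#' @param path SAM file path.
#' @return list with `junctions` (as in [align_fragments()]) and
#'   `n_skipped_unmapped`, `n_skipped_secondary`.
#' @export
load_sam <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq")
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  flag <- rec$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  keep <- !unmapped & !secondary
  qn <- rec$qname[keep]
  parts <- strsplit(qn, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    stop("SAM record lacks the readid|UMI|side|tag_end name convention: ",
         qn[bad[1L]])
  }
  n <- sum(keep)
  res <- vector("list", n)
  rname <- as.character(rec$rname)[keep]
  pos0 <- rec$pos[keep] - 1L           # SAM is 1-based
  strand <- as.character(rec$strand)[keep]
  width <- nchar(as.character(rec$seq)[keep])
  for (i in seq_len(n)) {
    pr <- parts[[i]]
    hit <- data.table(seq_name = rname[i], start = pos0[i],
                      strand = strand[i], mismatches = NA_integer_,
                      unique = TRUE)
    ## the aligner reverse-complemented minus-strand reads; tag_end given in
    ## original read space still resolves the junction as for built-in hits
    j <- junction_from_alignment(hit, width[i], pr[4L])
    res[[i]] <- data.table(read_id = pr[1L], umi = pr[2L],
                           seq_name = rname[i], junction_pos = j$pos,
                           side = j$side, strand = strand[i])
  }
  junctions <- rbindlist(res)
  if (!nrow(junctions)) {
    junctions <- data.table(read_id = character(), umi = character(),
                            seq_name = character(), junction_pos = integer(),
                            side = character(), strand = character())
  }
  list(junctions = junctions,
       n_skipped_unmapped = sum(unmapped),
       n_skipped_secondary = sum(secondary & !unmapped))
}

#' Write junction fragments as FASTA for an external aligner
#'
#' Emits fragments with the `readid|UMI|side|tag_end` name convention
#' expected back by [load_sam()].
#'
#' @param fragments `data.table` from [split_at_junction()].
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
write_fragments_fasta <- function(fragments, path) {
  x <- Biostrings::DNAStringSet(fragments$genomic_seq)
  names(x) <- paste(fragments$read_id, fragments$umi, fragments$side,
                    fragments$tag_end, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
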