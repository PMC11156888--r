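#' Read a pair of FASTQ files into a read-pair table
#'
#' Reads mate 1 and mate 2 FASTQ files (gzip handled transparently) and
#' returns one row per read pair. Records are taken in lockstep file order;
#' a mate-count mismatch is a hard error naming the first unmatched record.
#'
#' @param path_r1,path_r2 FASTQ file paths (optionally `.gz`).
#' @return a `data.table` with columns `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`. `read_id` is the first whitespace-delimited token of the R1
#'   header.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- read_fastq_one(path_r1)
  r2 <- read_fastq_one(path_r2)
  if (nrow(r1) != nrow(r2)) {
    stop(sprintf(
      "mate-count mismatch: %s has %d records, %s has %d (first unmatched record: %d)",
      path_r1, nrow(r1), path_r2, nrow(r2), min(nrow(r1), nrow(r2)) + 1L
    ))
  }
  data.table(
    read_id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
    seq2 = r2$seq, qual2 = r2$qual
  )
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    out <- data.table(
      id = sub("[ \t].*$", "", names(x)),
      seq = toupper(as.character(x)),
      qual = as.character(S4Vectors::mcols(x)$qualities)
    )
    if (any(nchar(out$seq) != nchar(out$qual))) {
      stop("sequence/quality length mismatch at record ",
           which(nchar(out$seq) != nchar(out$qual))[1L])
    }
    out
  }, error = function(e) {
    stop(sprintf("malformed FASTQ in %s: %s", path, conditionMessage(e)))
  })
}

#' Write a read-pair table back to paired FASTQ
#'
#' Inverse of [read_fastq_pairs()]; sequences and qualities round-trip
#' byte-identically. Paths ending in `.gz` are compressed.
#'
#' @param pairs read-pair `data.table` (see [read_fastq_pairs()]).
#' @param path_r1,path_r2 output paths.
#' @return invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, path_r1, path_r2) {
  write_fastq_one(pairs$read_id, pairs$seq1, pairs$qual1, path_r1)
  write_fastq_one(pairs$read_id, pairs$seq2, pairs$qual2, path_r2)
  invisible(c(path_r1, path_r2))
}

write_fastq_one <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(quals),
    compress = grepl("\\.gz$", path)
  )
}

#' Assign read pairs to samples by their 5' barcode
#'
#' The barcode is read from the 5' end of the designated mate (R1 by
#' default, matching a barcoded forward PCR primer). A pair is assigned to
#' the unique sample whose barcode lies within `max_barcode_mm` Hamming
#' mismatches; ties and non-matches go to the unassigned pool. Barcode bases
#' (sequence and quality) are trimmed from assigned reads. N bases count as
#' mismatches.
#'
#' @param pairs read-pair `data.table` from [read_fastq_pairs()].
#' @param samples `data.frame` with columns `sample_id` and `barcode`
#'   (equal-length, unique barcodes).
#' @param max_barcode_mm maximum Hamming distance for assignment (default 1).
#' @param barcode_mate which mate carries the barcode, `"R1"` or `"R2"`.
#' @return list with `samples` (named list of per-sample read-pair tables,
#'   barcode trimmed), `unassigned` (untrimmed table), and `report`
#'   (per-sample counts plus the unassigned total).
#' @export
demultiplex <- function(pairs, samples, max_barcode_mm = 1L, barcode_mate = "R1") {
  samples <- as.data.table(samples)
  stopifnot(all(c("sample_id", "barcode") %in% names(samples)))
  bl <- unique(nchar(samples$barcode))
  if (length(bl) != 1L) stop("all barcodes must have equal length")
  if (anyDuplicated(samples$barcode)) stop("barcodes must be unique per run")
  seq_col <- if (barcode_mate == "R1") "seq1" else "seq2"

  if (!nrow(pairs)) {
    empty <- pairs[0L]
    return(list(
      samples = setNames(rep(list(empty), nrow(samples)), samples$sample_id),
      unassigned = empty,
      report = data.table(sample_id = c(samples$sample_id, "unassigned"),
                          n_assigned = 0L)
    ))
  }
  ## pad reads shorter than the barcode so the char matrix stays rectangular
  prefix <- formatC(substr(pairs[[seq_col]], 1L, bl), width = bl, flag = "-")
  pm <- matrix(unlist(strsplit(prefix, "", fixed = TRUE)), nrow = bl)
  mm <- vapply(samples$barcode, function(bc) {
    colSums(pm != dna_chars(bc))
  }, numeric(nrow(pairs)))
  mm <- matrix(mm, nrow = nrow(pairs))

  best <- apply(mm, 1L, min)
  n_at_best <- rowSums(mm == best)
  assigned_idx <- best <= max_barcode_mm & n_at_best == 1L
  which_sample <- ifelse(assigned_idx, apply(mm, 1L, which.min), NA_integer_)

  out <- vector("list", nrow(samples))
  names(out) <- samples$sample_id
  for (i in seq_len(nrow(samples))) {
    sub <- pairs[which(which_sample == i)]
    if (nrow(sub)) {
      ## trim barcode bases from the designated mate
      if (barcode_mate == "R1") {
        sub[, `:=`(seq1 = substring(seq1, bl + 1L), qual1 = substring(qual1, bl + 1L))]
      } else {
        sub[, `:=`(seq2 = substring(seq2, bl + 1L), qual2 = substring(qual2, bl + 1L))]
      }
    }
    out[[i]] <- sub
  }
  unassigned <- pairs[which(is.na(which_sample))]
  report <- data.table(
    sample_id = c(samples$sample_id, "unassigned"),
    n_assigned = c(vapply(out, nrow, integer(1L)), nrow(unassigned))
  )
  list(samples = out, unassigned = unassigned, report = report)
}

#' Extract the molecular index (UMI) from demultiplexed reads
#'
#' The UMI is the first `umi_length` bases of the designated mate after
#' barcode removal (the adaptor places an 8-nt random molecular index at the
#' ligation junction). UMI bases are trimmed from the read; reads too short
#' to yield both a UMI and any sequence are dropped and counted, not an
#' error.
#'
#' @param pairs barcode-trimmed read-pair `data.table`.
#' @param umi_length UMI length in bases (default 8).
#' @param umi_mate mate carrying the UMI (`"R1"` default).
#' @return list with `reads` (table gaining a `umi` column, UMI trimmed from
#'   the mate) and `n_dropped`.
#' @export
extract_umi <- function(pairs, umi_length = 8L, umi_mate = "R1") {
  seq_col <- if (umi_mate == "R1") "seq1" else "seq2"
  qual_col <- if (umi_mate == "R1") "qual1" else "qual2"
  keep <- nchar(pairs[[seq_col]]) > umi_length
  reads <- pairs[keep]
  if (nrow(reads)) {
    reads[, umi := substr(get(seq_col), 1L, umi_length)]
    reads[, (seq_col) := substring(get(seq_col), umi_length + 1L)]
    reads[, (qual_col) := substring(get(qual_col), umi_length + 1L)]
  } else {
    reads[, umi := character()]
  }
  list(reads = reads, n_dropped = sum(!keep))
}
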