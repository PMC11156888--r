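mk_junctions <- function(pos, reads = 1L, umi = NULL, side = "left_of_tag",
                         seq_name = "chr1") {
  pos <- rep(pos, times = reads)
  n <- length(pos)
  data.table::data.table(
    read_id = sprintf("r%04d", seq_len(n)),
    umi = umi %||% sprintf("UMI%05d", seq_len(n)),
    seq_name = seq_name, junction_pos = pos,
    side = rep(side, length.out = n), strand = "+"
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("consolidation takes the read-weighted modal position, leftmost on ties", {
  j <- mk_junctions(c(1000L, 1000L, 1000L, 1004L, 1004L))
  s <- consolidate(j, merge_window = 10)
  expect_identical(nrow(s), 1L)
  expect_identical(s$position, 1000L)
  expect_identical(s$read_count, 5L)
  ## tie between 1000 and 1004 -> leftmost wins
  s2 <- consolidate(mk_junctions(c(1000L, 1000L, 1004L, 1004L)))
  expect_identical(s2$position, 1000L)
})

test_that("junctions separated beyond the merge window form distinct sites", {
  j <- mk_junctions(c(1000L, 1020L))
  expect_identical(nrow(consolidate(j, merge_window = 10)), 2L)
  expect_identical(nrow(consolidate(j, merge_window = 20)), 1L)
  ## single-linkage chains: 1000-1009-1018 all merge at window 10
  j3 <- mk_junctions(c(1000L, 1009L, 1018L))
  expect_identical(nrow(consolidate(j3, merge_window = 10)), 1L)
})

test_that("UMI deduplication counts distinct (umi, position, side) triples", {
  j <- mk_junctions(rep(1000L, 6),
                    umi = c("A", "A", "A", "B", "B", "C"))
  s <- consolidate(j)
  expect_identical(s$read_count, 6L)
  expect_identical(s$umi_count, 3L)
  ## same UMI on different sides stays distinct
  j2 <- mk_junctions(rep(1000L, 2), umi = c("A", "A"),
                     side = c("left_of_tag", "right_of_tag"))
  expect_identical(consolidate(j2)$umi_count, 2L)
  expect_identical(consolidate(j2)$side_left, 1L)
})

test_that("scan_target finds the exact frame and annotates planted mismatches", {
  set.seed(91)
  guide <- test_guide()
  left <- rand_dna(80)
  frame <- paste0(guide$protospacer, "AGG")
  chrom <- paste0(left, frame, rand_dna(80))
  ref <- c(chr1 = chrom)
  cut <- 80L + 20L - 3L  # blunt cut 3 bp 5' of the PAM

  hit <- scan_target(ref, "chr1", cut, guide)
  expect_identical(hit$mismatch_count, 0L)
  expect_identical(hit$target_strand, "+")
  expect_identical(hit$frame_start, 80L)
  expect_identical(hit$matched_seq, frame)

  ## planted 5-substitution frame: positions recovered exactly
  mmpos <- c(3L, 7L, 11L, 15L, 19L)
  frame5 <- paste0(mutate_at(guide$protospacer, mmpos), "TGG")
  chrom5 <- paste0(left, frame5, rand_dna(80))
  hit5 <- scan_target(c(chr1 = chrom5), "chr1", cut, guide)
  expect_identical(hit5$mismatch_count, 5L)
  expect_identical(hit5$mismatch_positions, mmpos - 1L)

  ## a reverse-strand frame is found with flipped coordinates
  chrom_rc <- paste0(left, revcomp(frame), rand_dna(80))
  hit_rc <- scan_target(c(chr1 = chrom_rc), "chr1", 80L + 3L + 3L, guide)
  expect_identical(hit_rc$mismatch_count, 0L)
  expect_identical(hit_rc$target_strand, "-")
})

test_that("frames beyond the mismatch budget are rejected", {
  set.seed(97)
  guide <- test_guide()
  frame8 <- paste0(mutate_at(guide$protospacer, sample(20, 8)), "AGG")
  chrom <- paste0(rand_dna(80), frame8, rand_dna(80))
  pos <- 97L
  h7 <- scan_target(c(chr1 = chrom), "chr1", pos, guide, max_mismatches = 7)
  h8 <- scan_target(c(chr1 = chrom), "chr1", pos, guide, max_mismatches = 8)
  ## the 8-mismatch frame only qualifies once the budget allows it (the
  ## random flanks hold nothing within 7)
  expect_null(h7)
  expect_identical(h8$mismatch_count, 8L)
})

test_that("scan_target matches the exhaustive oracle on random instances", {
  set.seed(101)
  n_agree <- 0L
  n_cases <- 120L
  for (i in seq_len(n_cases)) {
    proto <- rand_dna(20)
    guide <- guide_spec("g", proto, "NGG")
    chrom <- rand_dna(160)
    if (i %% 3 == 0) {  # plant a frame at a random offset, random strand
      k <- sample(0:7, 1)
      frame <- paste0(if (k) mutate_at(proto, sample(20, k)) else proto, "CGG")
      if (runif(1) < 0.5) frame <- revcomp(frame)
      off <- sample(40:90, 1)
      chrom <- paste0(substr(chrom, 1, off), frame, substring(chrom, off + 24))
    }
    pos <- 80L
    impl <- scan_target(c(c1 = chrom), "c1", pos, guide)
    ora <- oracle_scan_target(chrom, pos, guide)
    same <- if (is.null(impl)) is.null(ora) else {
      !is.null(ora) && impl$frame_start == ora$start &&
        impl$target_strand == ora$strand &&
        impl$mismatch_count == ora$mm && impl$matched_seq == ora$frame
    }
    n_agree <- n_agree + same
  }
  expect_identical(n_agree, n_cases)
})

test_that("raising the budget never removes a call; shrinking the flank never adds one", {
  set.seed(103)
  guide <- test_guide()
  n_found_lo <- 0L
  n_found_small <- 0L
  for (i in 1:30) {
    ch <- rand_dna(200)
    ## plant a frame of variable quality at a variable distance in most
    ## windows, so every branch of the property is exercised
    if (i %% 4 != 0) {
      frame <- paste0(mutate_at(guide$protospacer, sample(20, sample(4:9, 1))),
                      "GGG")
      off <- sample(c(80:95, 105:120), 1)
      ch <- paste0(substr(ch, 1, off), frame, substring(ch, off + 24))
    }
    ref <- c(c1 = ch)
    h_lo <- scan_target(ref, "c1", 100L, guide, max_mismatches = 7)
    h_hi <- scan_target(ref, "c1", 100L, guide, max_mismatches = 10)
    if (!is.null(h_lo)) {
      n_found_lo <- n_found_lo + 1L
      expect_false(is.null(h_hi))
      expect_lte(h_hi$mismatch_count, h_lo$mismatch_count)
    }
    f_small <- scan_target(ref, "c1", 100L, guide, flank = 10)
    f_big <- scan_target(ref, "c1", 100L, guide, flank = 25)
    if (!is.null(f_small)) {
      n_found_small <- n_found_small + 1L
      expect_false(is.null(f_big))
      expect_lte(f_big$mismatch_count, f_small$mismatch_count)
    }
  }
  ## both branches must actually have fired
  expect_gt(n_found_lo, 5L)
  expect_gt(n_found_small, 0L)
})

test_that("call_sites drops unmatchable sites and flags low read support", {
  set.seed(107)
  guide <- test_guide()
  frame0 <- paste0(guide$protospacer, "AGG")
  frame4 <- paste0(mutate_at(guide$protospacer, c(2, 6, 10, 14)), "AGG")
  chrom <- paste0(rand_dna(1000), frame0, rand_dna(1000), frame4,
                  rand_dna(1000))
  ref <- c(chr1 = chrom)
  on_cut <- 1000L + 17L
  off_cut <- 1000L + 23L + 1000L + 17L
  sites <- data.table::data.table(
    seq_name = "chr1",
    position = c(on_cut, off_cut, 2800L),
    window_start = c(on_cut, off_cut, 2800L),
    window_end = c(on_cut, off_cut, 2800L) + 1L,
    read_count = c(400L, 9L, 10L),
    umi_count = c(120L, 5L, 6L),
    side_left = c(200L, 5L, 5L), side_right = c(200L, 4L, 5L)
  )
  cs <- call_sites(sites, guide, ref,
                   on_target = list(seq_name = "chr1", position = on_cut))
  expect_identical(nrow(cs$calls), 2L)
  expect_identical(cs$n_dropped, 1L)
  expect_identical(cs$calls[position == on_cut]$is_on_target, TRUE)
  expect_identical(cs$calls[position == on_cut]$mismatch_count, 0L)
  expect_identical(cs$calls[position == off_cut]$mismatch_count, 4L)
  ## the low-support boundary sits exactly at 10 reads
  expect_true(cs$calls[read_count == 9]$low_read_flag)
  expect_false(cs$calls[read_count == 400]$low_read_flag)
  sites10 <- data.table::copy(sites)[2, read_count := 10L]
  cs10 <- call_sites(sites10, guide, ref,
                     on_target = list(seq_name = "chr1", position = on_cut))
  expect_false(cs10$calls[position == off_cut]$low_read_flag)
})

test_that("replicate confidence follows the two-replicate rule and keeps singletons", {
  mk_calls <- function(pos) {
    data.table::data.table(
      seq_name = "chr1", position = pos, target_strand = "+",
      read_count = 20L, mismatch_count = 3L, is_on_target = FALSE
    )
  }
  reps <- list(r1 = mk_calls(c(1000L, 5000L, 9000L)),
               r2 = mk_calls(c(1003L, 5002L)),
               r3 = mk_calls(c(1001L)))
  conf <- classify_confidence(reps, min_replicates = 2)
  expect_identical(nrow(conf), 3L)
  expect_identical(conf[position == 1001]$n_replicates_detected, 3L)
  expect_identical(conf[position == 1001]$confidence, "high")
  expect_identical(conf[position == 5001]$confidence, "high")
  ## the singleton is retained and labelled low, not discarded
  expect_identical(conf[position == 9000]$confidence, "low")

  ## permutation invariance in replicate order
  conf_perm <- classify_confidence(rev(reps), min_replicates = 2)
  expect_equal(conf[order(position)],
               conf_perm[order(position)])

  ## degenerate configuration: single replicate, min_replicates 1
  conf1 <- classify_confidence(reps["r1"], min_replicates = 1)
  expect_true(all(conf1$confidence == "high"))
})

test_that("off-index is the exact off/on read ratio", {
  calls <- data.table::data.table(
    read_count = c(400L, 30L, 10L),
    is_on_target = c(TRUE, FALSE, FALSE)
  )
  oi <- compute_off_index(calls)
  expect_identical(oi$value, 0.1)
  expect_identical(oi$off_reads_total, 40L)
  ## a sample with only the on-target call scores exactly zero
  oi0 <- compute_off_index(calls[is_on_target == TRUE])
  expect_identical(oi0$value, 0)
  ## no on-target call: undefined, with an explanation
  oiNA <- compute_off_index(calls[is_on_target == FALSE])
  expect_true(is.na(oiNA$value))
  expect_match(oiNA$explanation, "on-target")
})

test_that("site table renders dots for matches and letters at mismatches", {
  guide <- test_guide()
  perfect <- paste0(guide$protospacer, "TGG")
  mm_seq <- mutate_at(perfect, c(3, 8))
  set.seed(109)
  calls <- data.table::data.table(
    seq_name = "chr1", position = c(100L, 200L),
    window_start = c(100L, 200L), window_end = c(101L, 201L),
    read_count = c(50L, 20L), umi_count = c(10L, 5L),
    side_left = 1L, side_right = 1L,
    matched_seq = c(perfect, mm_seq), target_strand = "+",
    mismatch_count = c(0L, 2L), mismatch_positions = c("", "2,7"),
    frame_start = c(100L, 200L), implied_cut = c(100L, 200L),
    low_read_flag = FALSE, is_on_target = c(TRUE, FALSE)
  )
  tab <- render_site_table(calls, guide, format = "tsv")
  expect_match(tab[1], paste0("^", guide$protospacer, guide$pam, "\t"))
  row0 <- strsplit(tab[2], "\t")[[1]]
  expect_identical(row0[1], strrep(".", 23))
  row2 <- strsplit(tab[3], "\t")[[1]]
  disp <- strsplit(row2[1], "")[[1]]
  expect_identical(which(disp != "."), c(3L, 8L))
  expect_identical(disp[3], substr(mm_seq, 3, 3))
  ## TSV round-trip recovers the column values
  parsed <- data.table::fread(text = tab, sep = "\t")
  expect_identical(parsed$reads, c(50L, 20L))
  expect_identical(parsed$mismatches, c(0L, 2L))
  ## html mode wraps mismatches in colour spans
  html <- render_site_table(calls, guide, format = "html")
  expect_match(paste(html, collapse = ""), "<span style=\"color:red\">")
})
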