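test_that("length-excess windows classify exactly at their boundaries", {
  ## 34-nt tag: single 29-49, double 64-84; 39-nt: single 34-54, double 69-89
  cases <- rbind(
    data.frame(tag = 34, excess = c(29, 49), class = "single_insert"),
    data.frame(tag = 34, excess = c(64, 84), class = "double_insert"),
    data.frame(tag = 34, excess = c(28, 50, 63, 85), class = "edited_other"),
    data.frame(tag = 39, excess = c(34, 54), class = "single_insert"),
    data.frame(tag = 39, excess = c(69, 89), class = "double_insert"),
    data.frame(tag = 39, excess = c(33, 55, 68, 90), class = "edited_other")
  )
  got <- mapply(function(tag, excess) {
    classify_read(200L + excess, 200L, tag, insertion_present = TRUE)
  }, cases$tag, cases$excess)
  expect_identical(unname(got), cases$class)
  ## worked example from the window arithmetic
  expect_identical(classify_read(239L, 200L, 34L, TRUE), "single_insert")
  expect_identical(classify_read(274L, 200L, 34L, TRUE), "double_insert")
  expect_identical(classify_read(244L, 200L, 39L, TRUE), "single_insert")
  expect_identical(classify_read(200L, 200L, 34L, FALSE), "unedited")
  expect_identical(classify_read(228L, 200L, 34L, TRUE), "edited_other")
  ## unsupported tag length without explicit windows is an error
  expect_error(classify_read(250L, 200L, 46L, TRUE), "windows")
  expect_identical(
    classify_read(250L, 200L, 46L, TRUE,
                  windows = list(single = c(41L, 61L), double = c(86L, 106L))),
    "single_insert"
  )
})

test_that("the four read classes partition every input", {
  set.seed(113)
  n <- 10000
  read_len <- 200L + sample(-20:100, n, replace = TRUE)
  ins <- sample(c(TRUE, FALSE), n, replace = TRUE)
  cls <- classify_read(read_len, 200L, 39L, ins)
  expect_identical(length(cls), as.integer(n))
  expect_true(all(cls %in% c("unedited", "single_insert", "double_insert",
                             "edited_other")))
  tab <- table(factor(cls, levels = c("unedited", "single_insert",
                                      "double_insert", "edited_other")))
  expect_identical(sum(tab), as.integer(n))
  expect_identical(sum(cls == "unedited"), sum(!ins))
})

test_that("tag blocks are detected down to the minimum fragment", {
  set.seed(127)
  dso <- test_dsodn()
  ref <- simulate_amplicon_reference(240, dso)
  expect_true(has_insertion(paste0(substr(ref, 1, 120), dso$sequence,
                                   substring(ref, 121)), dso))
  expect_false(has_insertion(ref, dso))
  ## a 12-nt truncated fragment still counts as an insertion
  blk <- substr(dso$sequence, 14, 25)
  expect_true(has_insertion(paste0(substr(ref, 1, 120), blk,
                                   substring(ref, 121)), dso))
  ## reverse-orientation block too
  expect_true(has_insertion(paste0(substr(ref, 1, 120), revcomp(blk),
                                   substring(ref, 121)), dso))
})

test_that("target-read selection keeps anchor-bearing reads on either strand", {
  set.seed(131)
  dso <- test_dsodn()
  ref <- simulate_amplicon_reference(240, dso)
  spec <- amplicon_spec("s", ref, substr(ref, 40, 59), dso)
  expect_true(select_target_reads(ref, spec))
  expect_true(select_target_reads(revcomp(ref), spec))
  expect_false(select_target_reads(rand_dna(240), spec))
  ## contaminated pool: kept fraction tracks the planted 90% within 3 sigma
  pool <- simulate_amplicon_pool(spec, n = 1000, seed = 17,
                                 contaminant_fraction = 0.1)
  kept <- mean(select_target_reads(pool$seqs, spec))
  p <- 1000 / length(pool$seqs)
  expect_lt(abs(kept - p), 3 * sqrt(p * (1 - p) / length(pool$seqs)))
})

test_that("summarize_amplicon reproduces the worked frequency arithmetic", {
  set.seed(137)
  dso <- test_dsodn()
  ref <- simulate_amplicon_reference(240, dso)
  spec <- amplicon_spec("s", ref, substr(ref, 40, 59), dso)
  cut <- spec$cut_pos
  tag <- dso$sequence
  ## 10 target reads: 6 unedited, 3 single (one truncated but in-window via
  ## mutated tail), 1 double; 2 of the 4 inserted reads carry the full oligo
  insert <- function(piece) paste0(substr(ref, 1, cut), piece,
                                   substring(ref, cut + 1))
  reads <- c(
    rep(ref, 6),
    insert(tag),                                   # single, full
    insert(mutate_at(tag, 35:39)),                 # single, not full
    insert(mutate_at(tag, 34:39)),                 # single, not full
    insert(paste0(tag, tag))                       # double, full
  )
  s <- summarize_amplicon(reads, spec)
  expect_identical(s$n_total_target_reads, 10L)
  expect_identical(s$n_unedited, 6L)
  expect_identical(s$n_single_insert, 3L)
  expect_identical(s$n_double_insert, 1L)
  expect_identical(s$insertion_frequency, 0.4)
  expect_identical(s$full_length_rate, 0.5)
  ## no insertions: the full-length rate is flagged undefined
  s0 <- summarize_amplicon(rep(ref, 5), spec)
  expect_identical(s0$n_unedited, 5L)
  expect_true(is.na(s0$full_length_rate))
  expect_false(s0$full_length_defined)
  ## the empty pool gives zero counts, not an error
  s_empty <- summarize_amplicon(character(), spec)
  expect_identical(s_empty$n_total_target_reads, 0L)
})

test_that("edited_other never contributes to the insertion frequency", {
  set.seed(139)
  dso <- test_dsodn()
  ref <- simulate_amplicon_reference(240, dso)
  spec <- amplicon_spec("s", ref, substr(ref, 40, 59), dso)
  cut <- spec$cut_pos
  ## adversarial pool: only truncated (out-of-window) insertions
  blk <- substr(dso$sequence, 1, 20)
  reads <- c(rep(ref, 5),
             rep(paste0(substr(ref, 1, cut), blk, substring(ref, cut + 1)), 5))
  s <- summarize_amplicon(reads, spec)
  expect_identical(s$n_edited_other, 5L)
  expect_identical(s$insertion_frequency, 0)
  expect_identical(s$full_length_rate, 0)
})

test_that("overlapping pairs merge into the spanning amplicon sequence", {
  set.seed(149)
  full <- rand_dna(260)
  s1 <- substr(full, 1, 150)
  s2 <- revcomp(substring(full, 111))  # mate 2 in sequencing orientation
  expect_identical(merge_read_pair(s1, s2), full)
  ## two errors in the overlap are tolerated, three are not at default
  s1_err <- mutate_at(s1, c(120, 130))
  expect_identical(nchar(merge_read_pair(s1_err, s2)), 260L)
  expect_true(is.na(merge_read_pair(rand_dna(150), s2)))
})

test_that("a seeded pool recovers its planted fractions and full-length rate", {
  set.seed(151)
  dso <- test_dsodn()
  ref <- simulate_amplicon_reference(240, dso)
  spec <- amplicon_spec("ampX", ref, substr(ref, 40, 59), dso)
  fr <- c(unedited = 0.60, single_insert = 0.25, double_insert = 0.10,
          edited_other = 0.05)
  pool <- simulate_amplicon_pool(spec, fractions = fr,
                                 full_length_fraction = 0.7,
                                 n = 2000, seed = 19)
  s <- summarize_amplicon(pool$seqs, spec)
  n <- s$n_total_target_reads
  est <- c(unedited = s$n_unedited, single_insert = s$n_single_insert,
           double_insert = s$n_double_insert,
           edited_other = s$n_edited_other) / n
  for (cl in names(fr)) {
    tol <- 3 * sqrt(fr[[cl]] * (1 - fr[[cl]]) / n)
    expect_lt(abs(est[[cl]] - fr[[cl]]), tol)
  }
  ## rate definitions hold against the per-read truth
  truth_ins <- pool$truth$class %in% c("single_insert", "double_insert")
  expect_identical(s$insertion_frequency,
                   (s$n_single_insert + s$n_double_insert) / n)
  any_ins <- s$n_single_insert + s$n_double_insert + s$n_edited_other
  expect_identical(s$full_length_rate, s$n_full_length / any_ins)
  p_fl <- 0.7
  expect_lt(abs(s$full_length_rate - p_fl),
            3 * sqrt(p_fl * (1 - p_fl) / any_ins))
})
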