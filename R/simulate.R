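#' Simulation configuration for a tagged-break discovery library
#'
#' Bundles the study conditions the generator emulates: a 100 kb uniform
#' background genome carrying one planted on-target and a plan of
#' off-target frames; molecules sheared to 500-700 bp with the dsODN
#' captured blunt at the cut in random orientation; 150 bp paired-end reads
#' with a sample barcode and an 8-nt molecular index on read 1; tandem
#' integrations at low probability (0-0.10), occasional tag truncation,
#' and uniform substitution error.
#'
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param guide a [guide_spec()].
#' @param dsodn a [dsodn_spec()].
#' @param genome_length background genome length (default 100000).
#' @param offtarget_plan `data.frame` with columns `mismatches` (1-8, the
#'   exact planted mismatch count) and `molecules` (tagged molecules at the
#'   site). Default: 20 off-targets spanning mismatch counts 1-7 with
#'   abundance declining as mismatches rise.
#' @param on_target_molecules tagged molecules at the on-target
#'   (default 60; on-target cleavage dominates).
#' @param fragment_range sheared fragment length range (default 500-700).
#' @param read_length read length (default 150).
#' @param umi_length molecular index length (default 8).
#' @param barcode sample barcode placed 5' on read 1 (default `"ACGTAC"`).
#' @param tandem_insertion_prob per-molecule tandem (double tag)
#'   probability, in `[0, 0.10]` (default 0.05).
#' @param truncation_prob per-molecule probability of a 3'-truncated tag
#'   (default 0.10).
#' @param substitution_error_rate per-base substitution rate (default
#'   0.001).
#' @param background_fraction fraction of reads that are untagged genomic
#'   background (default 0.5), exercising tag-detection specificity.
#' @param duplicate_rate Poisson mean of extra reads per molecule (PCR
#'   duplicates sharing the molecule's UMI; default 0.6).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed, guide, dsodn, genome_length = 100000L,
                       offtarget_plan = default_offtarget_plan(),
                       on_target_molecules = 60L,
                       fragment_range = c(500L, 700L),
                       read_length = 150L, umi_length = 8L,
                       barcode = "ACGTAC",
                       tandem_insertion_prob = 0.05,
                       truncation_prob = 0.10,
                       substitution_error_rate = 0.001,
                       background_fraction = 0.5,
                       duplicate_rate = 0.6) {
  offtarget_plan <- as.data.table(offtarget_plan)
  stopifnot(
    inherits(guide, "guide_spec"), inherits(dsodn, "dsodn_spec"),
    all(c("mismatches", "molecules") %in% names(offtarget_plan)),
    all(offtarget_plan$mismatches >= 1L & offtarget_plan$mismatches <= 8L),
    tandem_insertion_prob >= 0, tandem_insertion_prob <= 0.10,
    truncation_prob >= 0, truncation_prob <= 1,
    substitution_error_rate >= 0, substitution_error_rate <= 1,
    background_fraction >= 0, background_fraction < 1
  )
  structure(list(
    seed = as.integer(seed), guide = guide, dsodn = dsodn,
    genome_length = as.integer(genome_length),
    offtarget_plan = offtarget_plan,
    on_target_molecules = as.integer(on_target_molecules),
    fragment_range = as.integer(fragment_range),
    read_length = as.integer(read_length),
    umi_length = as.integer(umi_length), barcode = barcode,
    tandem_insertion_prob = tandem_insertion_prob,
    truncation_prob = truncation_prob,
    substitution_error_rate = substitution_error_rate,
    background_fraction = background_fraction,
    duplicate_rate = duplicate_rate
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_offtarget_plan <- function() {
  mm <- rep(1:7, length.out = 20L)
  data.table(mismatches = sort(mm), molecules = pmax(12L, 36L - 3L * sort(mm)))
}

## replace bases at 1-based positions with a different random base each
mutate_bases <- function(seq, positions) {
  ch <- dna_chars(seq)
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

## one concrete PAM drawn from the pattern (N and degenerate codes resolved)
concrete_pam <- function(pam) {
  paste(vapply(dna_chars(pam), function(p) {
    sample(dna_chars(Biostrings::IUPAC_CODE_MAP[[p]]), 1L)
  }, character(1L)), collapse = "")
}

#' Simulate a genome with planted on- and off-target frames
#'
#' Draws an i.i.d. uniform ACGT background, plants the exact
#' protospacer+PAM once, and plants one frame per off-target plan row with
#' exactly its declared mismatch count (mismatches confined to the
#' protospacer; the PAM stays pattern-valid) at non-overlapping positions
#' at least 1 kb apart, alternating strands. The blunt-cut coordinate
#' implied by each frame is recorded as the site truth.
#'
#' @param cfg a [sim_config()].
#' @return a `genome_sim` list: `genome` (named character vector, one
#'   contig `"chr_sim"`), `truth` (per-site `data.table`: `site_id`,
#'   `seq_name`, `strand`, `frame_start`, `cut_pos`, `planted_seq`,
#'   `mismatches`, `mismatch_positions`, `molecules`), and `cfg`.
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  g <- cfg$guide
  plen <- nchar(g$protospacer)
  pamlen <- nchar(g$pam)
  F <- plen + pamlen
  plan <- cfg$offtarget_plan
  n_sites <- nrow(plan) + 1L

  spacing <- cfg$genome_length %/% (n_sites + 1L)
  if (spacing < 1000L + 200L) {
    stop("cannot place ", n_sites, " sites >=1 kb apart in a ",
         cfg$genome_length, " bp genome")
  }
  genome <- random_dna(1L, cfg$genome_length)

  frame_starts <- spacing * seq_len(n_sites) + sample(-50:50, n_sites, TRUE)
  strands <- rep(c("+", "-"), length.out = n_sites)

  truth <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    if (i == 1L) {
      mm_n <- 0L
      mm_pos <- integer()
      frame <- paste0(g$protospacer, concrete_pam(g$pam))
      mols <- cfg$on_target_molecules
    } else {
      mm_n <- as.integer(plan$mismatches[i - 1L])
      mm_pos <- sort(sample.int(plen, mm_n))
      frame <- paste0(mutate_bases(g$protospacer, mm_pos), concrete_pam(g$pam))
      mols <- as.integer(plan$molecules[i - 1L])
    }
    s <- frame_starts[i]
    planted <- if (strands[i] == "+") frame else revcomp(frame)
    genome <- paste0(substr(genome, 1L, s), planted,
                     substring(genome, s + F + 1L))
    cut <- if (strands[i] == "+") s + plen - g$cut_offset else
      s + pamlen + g$cut_offset
    truth[[i]] <- data.table(
      site_id = if (i == 1L) "on_target" else sprintf("off_%02d", i - 1L),
      seq_name = "chr_sim", strand = strands[i],
      frame_start = as.integer(s), cut_pos = as.integer(cut),
      planted_seq = frame, mismatches = mm_n,
      mismatch_positions = paste(mm_pos - 1L, collapse = ","),
      molecules = mols
    )
  }
  truth <- rbindlist(truth)

  ## the on-target frame must be unique in the genome (collision with the
  ## random background is astronomically unlikely; fail loudly if it happens)
  on_frame <- truth$planted_seq[1L]
  n_occ <- Biostrings::countPattern(on_frame, Biostrings::DNAString(genome)) +
    Biostrings::countPattern(revcomp(on_frame), Biostrings::DNAString(genome))
  if (n_occ != 1L) stop("on-target frame not unique in simulated genome")

  structure(list(genome = c(chr_sim = genome), truth = truth, cfg = cfg),
            class = "genome_sim")
}

#' Write a simulated genome to FASTA
#'
#' @param sim a `genome_sim` from [simulate_genome()].
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
write_genome_fasta <- function(sim, path) {
  x <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Simulate a tagged-break discovery library
#'
#' Emits barcoded, UMI-tagged 150 bp read pairs from sheared 500-700 bp
#' fragments carrying the dsODN captured blunt at each planted cut
#' (orientation random per molecule; truncated or tandem at the configured
#' probabilities), plus untagged background fragments. The junction is
#' placed 30-90 bp from the sequenced fragment end so it falls inside read
#' 1, emulating the junction-proximal enrichment of the tag-primed PCR.
#' PCR duplicates are emitted as extra reads sharing a molecule's UMI;
#' UMIs are drawn without replacement within a site (the 4^8 space dwarfs
#' per-site molecule counts).
#'
#' @param sim a `genome_sim` from [simulate_genome()].
#' @param seed seed for the library stage (default `cfg$seed + 1`).
#' @return list: `pairs` (read-pair `data.table` as from
#'   [read_fastq_pairs()]), `truth_reads` (per-read truth: `read_id`,
#'   `site_id`, `molecule_id`, `umi`, `side`, `orientation`, `full_length`,
#'   `tandem`, `cut_pos`), `n_tagged_reads`, `n_background`.
#' @export
simulate_discovery_library <- function(sim, seed = NULL) {
  cfg <- sim$cfg
  set.seed(seed %||% (cfg$seed + 1L))
  genome <- sim$genome[[1L]]
  G <- nchar(genome)
  tag <- cfg$dsodn$sequence
  tlen <- nchar(tag)
  bl <- nchar(cfg$barcode)
  core_len <- cfg$read_length - bl - cfg$umi_length

  rows <- list()
  truth <- list()
  for (si in seq_len(nrow(sim$truth))) {
    st <- sim$truth[si]
    m <- st$molecules
    umis <- int_to_dna(sample.int(4L^cfg$umi_length, m, replace = FALSE),
                       cfg$umi_length)
    for (mi in seq_len(m)) {
      ori <- sample(c("forward", "reverse"), 1L)
      tandem <- runif(1L) < cfg$tandem_insertion_prob
      truncated <- !tandem && runif(1L) < cfg$truncation_prob
      ins <- tag
      if (tandem) ins <- paste0(tag, tag)
      if (truncated) {
        ins <- substr(tag, 1L, sample(cfg$dsodn$anchor_length:(tlen - 5L), 1L))
      }
      if (ori == "reverse") ins <- revcomp(ins)
      side <- sample(c("left", "right"), 1L)
      flank_len <- sample(30:90, 1L)
      fraglen <- sample(cfg$fragment_range[1L]:cfg$fragment_range[2L], 1L)
      cut <- st$cut_pos
      if (side == "left") {
        fstart <- cut - flank_len
        fend <- min(G, fstart + fraglen)
      } else {
        fend <- cut + flank_len
        fstart <- max(0L, fend - fraglen)
      }
      mol_seq <- paste0(substr(genome, fstart + 1L, cut), ins,
                        substr(genome, cut + 1L, fend))
      template <- if (side == "left") mol_seq else revcomp(mol_seq)
      r1_core <- substr(template, 1L, core_len)
      r2 <- substr(revcomp(template), 1L, cfg$read_length)
      n_reads <- 1L + rpois(1L, cfg$duplicate_rate)
      for (ri in seq_len(n_reads)) {
        rid <- sprintf("%s_m%04d_r%d", st$site_id, mi, ri)
        r1 <- paste0(cfg$barcode, umis[mi],
                     apply_substitution_errors(r1_core,
                                               cfg$substitution_error_rate))
        r2e <- apply_substitution_errors(r2, cfg$substitution_error_rate)
        rows[[length(rows) + 1L]] <- data.table(
          read_id = rid, seq1 = r1, qual1 = strrep("I", nchar(r1)),
          seq2 = r2e, qual2 = strrep("I", nchar(r2e))
        )
        truth[[length(truth) + 1L]] <- data.table(
          read_id = rid, site_id = st$site_id, molecule_id = mi,
          umi = umis[mi],
          side = if (side == "left") "left_of_tag" else "right_of_tag",
          orientation = ori, full_length = !truncated, tandem = tandem,
          cut_pos = cut
        )
      }
    }
  }
  n_tagged <- length(rows)

  ## untagged genomic background
  n_bg <- round(cfg$background_fraction / (1 - cfg$background_fraction) *
                  n_tagged)
  for (bi in seq_len(n_bg)) {
    fraglen <- sample(cfg$fragment_range[1L]:cfg$fragment_range[2L], 1L)
    fstart <- sample.int(G - fraglen, 1L) - 1L
    frag <- substr(genome, fstart + 1L, fstart + fraglen)
    umi <- int_to_dna(sample.int(4L^cfg$umi_length, 1L), cfg$umi_length)
    rid <- sprintf("bg_%06d", bi)
    r1 <- paste0(cfg$barcode, umi,
                 apply_substitution_errors(substr(frag, 1L, core_len),
                                           cfg$substitution_error_rate))
    r2 <- apply_substitution_errors(substr(revcomp(frag), 1L, cfg$read_length),
                                    cfg$substitution_error_rate)
    rows[[length(rows) + 1L]] <- data.table(
      read_id = rid, seq1 = r1, qual1 = strrep("I", nchar(r1)),
      seq2 = r2, qual2 = strrep("I", nchar(r2))
    )
  }

  pairs <- rbindlist(rows)
  ## shuffle so file order carries no site signal
  pairs <- pairs[sample.int(nrow(pairs))]
  list(pairs = pairs, truth_reads = rbindlist(truth),
       n_tagged_reads = n_tagged, n_background = n_bg)
}

#' Simulate a targeted-amplicon read pool with planted editing outcomes
#'
#' Generates spanning amplicon reads whose class fractions, tag content and
#' full-length status are all recorded as truth. Single- and
#' double-insertion reads gain exactly one or two tag lengths; their
#' non-full-length variants carry tags with mutated terminal bases
#' (junction-indel surrogate) so the length class is preserved while the
#' complete oligo is absent. `edited_other` reads carry either a short
#' truncated tag block (length below the single window) or, when drawn
#' full-length, a complete tag plus junction fill pushing the excess
#' between the single and double windows.
#'
#' @param spec an [amplicon_spec()].
#' @param fractions named numeric summing to 1 over classes `unedited`,
#'   `single_insert`, `double_insert`, `edited_other`.
#' @param full_length_fraction probability that an insertion-bearing read
#'   contains the complete oligo (default 0.7).
#' @param n number of reads (default 2000).
#' @param seed integer seed.
#' @param error_rate per-base substitution rate (default 0).
#' @param contaminant_fraction extra off-amplicon reads emitted as this
#'   fraction of the total pool (default 0).
#' @return list: `seqs` (character vector), `truth` (`data.table`:
#'   `read_id`, `class`, `full_length`), `spec`.
#' @export
simulate_amplicon_pool <- function(spec,
                                   fractions = c(unedited = 0.60,
                                                 single_insert = 0.25,
                                                 double_insert = 0.10,
                                                 edited_other = 0.05),
                                   full_length_fraction = 0.7,
                                   n = 2000L, seed = 1L, error_rate = 0,
                                   contaminant_fraction = 0) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  ref <- spec$reference_amplicon
  cut <- spec$cut_pos
  tag <- spec$dsodn$sequence
  tlen <- nchar(tag)
  w <- insertion_windows(tlen)

  n_cont <- round(n * contaminant_fraction)
  classes <- sample(names(fractions), n, replace = TRUE, prob = fractions)
  seqs <- character(n + n_cont)
  full <- logical(n + n_cont)
  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl == "unedited") {
      seqs[i] <- ref
      next
    }
    is_full <- runif(1L) < full_length_fraction
    full[i] <- is_full
    ori_tag <- if (runif(1L) < 0.5) tag else revcomp(tag)
    ins <- switch(cl,
      single_insert = if (is_full) ori_tag else
        mutate_bases(ori_tag, (tlen - sample(3:8, 1L) + 1L):tlen),
      double_insert = if (is_full) paste0(ori_tag, ori_tag) else {
        d <- sample(3:8, 1L)
        mut <- mutate_bases(ori_tag, (tlen - d + 1L):tlen)
        paste0(mut, mutate_bases(ori_tag, 1:d))
      },
      edited_other = if (is_full) {
        ## complete tag plus junction fill landing between the windows
        fill <- sample((w$single[2L] + 2L - tlen):(w$double[1L] - 2L - tlen), 1L)
        paste0(ori_tag, random_dna(1L, fill))
      } else {
        substr(ori_tag, 1L, sample(12:(w$single[1L] - 2L), 1L))
      }
    )
    seqs[i] <- paste0(substr(ref, 1L, cut), ins, substring(ref, cut + 1L))
  }
  for (i in seq_len(n_cont)) {
    seqs[n + i] <- random_dna(1L, nchar(ref))
  }
  classes <- c(classes, rep("off_amplicon", n_cont))
  if (error_rate > 0) seqs <- apply_substitution_errors(seqs, error_rate)
  list(
    seqs = seqs,
    truth = data.table(read_id = sprintf("amp_%05d", seq_along(seqs)),
                       class = classes, full_length = full),
    spec = spec
  )
}

#' Draw a random amplicon reference free of dsODN cross-matches
#'
#' Rejection-samples a uniform random sequence until no tag block of
#' `min_fragment` bases matches within `max_mm` (the [has_insertion()]
#' criterion), mirroring real assay design where amplicons are checked
#' against the tag. Uses the current RNG state.
#'
#' @param len reference length (200-280 bp is typical).
#' @param dsodn a [dsodn_spec()].
#' @param min_fragment,max_mm the detection tolerance to stay clear of.
#' @return a reference sequence string.
#' @export
simulate_amplicon_reference <- function(len, dsodn, min_fragment = 10L,
                                        max_mm = 1L) {
  for (i in 1:100) {
    ref <- random_dna(1L, len)
    if (!has_insertion(ref, dsodn, min_fragment = min_fragment,
                       max_mm = max_mm)) {
      return(ref)
    }
  }
  stop("could not draw a tag-clean amplicon reference")
}

#' Write single-end reads to FASTQ
#'
#' @param ids,seqs read names and sequences.
#' @param path output path (`.gz` compressed).
#' @return invisibly, `path`.
#' @export
write_fastq_single <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}
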