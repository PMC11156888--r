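## Shared fixtures: a small guide/tag pair used across tests, plus tiny
## builders. All randomness is seeded inside each test.

TEST_TAG39 <- "ACGATGACGTCTAGCTACGATCGATCAGTCAGGCATGCA"
TEST_TAG34 <- substr(TEST_TAG39, 1L, 34L)
TEST_PROTO <- "GAGTCCGAGCAGAAGAAGAA"

test_guide <- function() guide_spec("g_test", TEST_PROTO, "NGG")
test_dsodn <- function(len = 39L) {
  dsodn_spec(paste0("tag", len), substr(TEST_TAG39, 1L, len))
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## mutate exactly `positions` (1-based) to a different base each
mutate_at <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1L]]
  for (p in positions) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

## a small simulation config shared by pipeline-level tests
small_sim_config <- function(seed, n_off = 5L, molecules = 12L,
                             error = 0, genome_length = 40000L, ...) {
  sim_config(
    seed = seed, guide = test_guide(), dsodn = test_dsodn(),
    genome_length = genome_length,
    offtarget_plan = data.frame(mismatches = rep(1:7, length.out = n_off),
                                molecules = molecules),
    on_target_molecules = 30L,
    substitution_error_rate = error,
    ...
  )
}

## run the discovery stages (demux .. call) over a simulated library and
## return everything a test may want to inspect
run_discovery <- function(sim, lib, max_mismatches = 7L) {
  dmx <- demultiplex(lib$pairs,
                     data.frame(sample_id = "s1", barcode = sim$cfg$barcode))
  um <- extract_umi(dmx$samples$s1, umi_length = sim$cfg$umi_length)
  hits <- find_tag(um$reads$seq1, sim$cfg$dsodn)
  frags <- split_at_junction(um$reads, hits, sim$cfg$dsodn)
  idx <- build_index(sim$genome, k = 20L)
  aln <- align_fragments(frags, idx)
  sites <- consolidate(aln$junctions)
  cs <- call_sites(sites, sim$cfg$guide, idx,
                   max_mismatches = max_mismatches,
                   on_target = list(seq_name = "chr_sim",
                                    position = sim$truth$cut_pos[1L]))
  list(reads = um$reads, hits = hits, frags = frags, index = idx,
       junctions = aln$junctions, sites = sites, calls = cs$calls,
       n_dropped = cs$n_dropped)
}
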