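---
title: "Discovering dsODN-tagged Cas9 breaks: models, parameters and design choices"
author: "breaktag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering dsODN-tagged Cas9 breaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breaktag)
```

## The assay and the computational problem

CRISPR-Cas9 cleaves its intended genomic target and, at lower frequency,
near-cognate off-target loci. Tag-integration assays detect those cleavage
events in living cells: a short blunt double-stranded oligodeoxynucleotide
(dsODN, 34 or 39 nt in the designs supported here, 46 nt also accepted) is
delivered together with the nuclease and is captured into double-strand
breaks by non-homologous end joining. Every genomic position where the tag
is found afterwards marks a break. Sequencing libraries are built from
sheared genomic DNA (500–700 bp fragments) with a ligated adaptor carrying
an 8-nt random molecular index (UMI), and tag-directed PCR enriches
fragments that span a tag–genome junction. The result is 150 bp paired-end
reads in which read 1 carries, in order: a sample barcode, the UMI, a
stretch of genomic sequence, and (for informative reads) part or all of
the tag.

`breaktag` turns those reads into an annotated off-target catalogue in six
stages, each exposed as ordinary functions so every stage is testable in
isolation:

1. **Demultiplex and UMI extraction** (`demultiplex()`, `extract_umi()`) —
   barcodes are matched at the 5' end of read 1 with a Hamming tolerance
   (default 1); ambiguous reads go to an unassigned pool rather than being
   guessed. The UMI is the next 8 bases.
2. **Tag scanning** (`find_tag()`, `split_at_junction()`) — the
   junction-proximal 12 bases of the tag (the *anchor*) and their reverse
   complement are located anywhere in the read; the genomic flank on the
   junction side becomes an alignable fragment labelled with the side of
   the tag it came from.
3. **Alignment** (`build_index()`, `align_fragments()`, or `load_sam()`
   for external aligners) — exact 20-mer seeds plus ungapped extension
   place each fragment; the junction coordinate is the insertion point
   adjacent to the tag, derived from the alignment strand and which
   fragment end touched the tag.
4. **Consolidation** (`consolidate()`) — junctions within 10 bp
   single-linkage merge into one cleavage site; molecules are counted as
   distinct `(UMI, junction, side)` triples, collapsing PCR duplicates.
5. **Off-target nomination** (`scan_target()`, `call_sites()`) — a frame
   of protospacer+PAM length slides over ±25 bp around each site on both
   strands; the best frame under a combined mismatch budget (default 7
   across target *and* PAM, pattern-N positions free) annotates the call.
6. **Replicate confidence and off-index** (`classify_confidence()`,
   `compute_off_index()`) — loci detected in at least two biological
   replicates are high-confidence; singletons are retained as
   low-confidence. The off-index is the ratio of summed off-target reads
   to on-target reads, a per-sample scalar summarizing relative
   off-target activity.

A companion module (`summarize_amplicon()`) quantifies dsODN insertion
outcomes in targeted amplicon sequencing, and `sim_config()` /
`simulate_genome()` / `simulate_discovery_library()` /
`simulate_amplicon_pool()` generate fully specified synthetic datasets
with ground truth.

## A complete run on simulated data

```{r, eval = FALSE}
guide <- guide_spec("EMX1-like", "GAGTCCGAGCAGAAGAAGAA", pam = "NGG")
dso <- dsodn_spec("tag39", "ACGATGACGTCTAGCTACGATCGATCAGTCAGGCATGCA")

cfg <- sim_config(
  seed = 42, guide = guide, dsodn = dso,
  offtarget_plan = data.frame(mismatches = rep(1:7, length.out = 20),
                              molecules = 15),
  on_target_molecules = 60,
  substitution_error_rate = 0.005
)
sim <- simulate_genome(cfg)
lib <- simulate_discovery_library(sim)

dmx <- demultiplex(lib$pairs, data.frame(sample_id = "s1",
                                         barcode = cfg$barcode))
um <- extract_umi(dmx$samples$s1)
hits <- find_tag(um$reads$seq1, dso)
frags <- split_at_junction(um$reads, hits, dso)
idx <- build_index(sim$genome, k = 20)
aln <- align_fragments(frags, idx)
sites <- consolidate(aln$junctions)
cs <- call_sites(sites, guide, idx,
                 on_target = list(seq_name = "chr_sim",
                                  position = sim$truth$cut_pos[1]))
writeLines(render_site_table(cs$calls, guide, "text"))
compute_off_index(cs$calls)
```

The same flow runs from a YAML manifest via `run_pipeline()` (or the
`inst/cli/breaktag.R` script), which also writes per-stage TSVs, a sites
BED, the rendered site table and a log carrying the conservation identity
of each stage (reads in = reads out + dropped).

## The mismatch model

A candidate frame is the concatenation of a 20-nt protospacer match and
the PAM. A mismatch is either a base differing from the protospacer or a
PAM base violating the PAM pattern; IUPAC codes in the pattern define the
allowed set and pattern `N` matches everything at no cost. The budget is a
single combined Hamming count over the whole frame (default 7,
configurable; 6 reproduces the stricter convention used by related
46-nt-tag pipelines). We chose the combined budget over separate
per-region budgets because the phrase "mismatches in both target and PAM
sequences" is ambiguous, and the combined reading matches the related
criterion of comparable pipelines; both the total and the interpretation
are configurable (`max_mismatches`).

Tie-breaking when several frames share the minimal count: the frame whose
implied blunt cut (3 bp 5' of the PAM, standard for SpCas9) is closest to
the consolidated junction wins, then the + strand, then the leftmost
frame. The cut offset is used only for tie-breaking and simulation; it
does not affect mismatch counting. The scanner is verified against an
independent exhaustive per-character oracle on hundreds of random
instances in the test suite.

Bulge/gap-tolerant matching (insertions or deletions between the DNA and
the guide) is deliberately out of scope; loci matching only with a bulge
will not be annotated.

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `max_barcode_mm` | 1 | barcode Hamming tolerance; ties go to unassigned. N counts as a mismatch (conservative). |
| `umi_length` | 8 nt | length of the adaptor's random molecular index. |
| `anchor_length` | 12 nt | tag bases used for detection; long enough to be specific in a 10^5 bp test genome, short enough to survive truncated integrations. |
| `max_anchor_mm` | 1 | one sequencing error in the anchor is absorbed. |
| `min_fragment_length` | 25 bp | smallest genomic flank worth aligning; shorter flanks are too ambiguous at genome scale. |
| `k` (seed) | 20 | exact-seed length of the built-in aligner. |
| `max_align_mm` | 3 | per-fragment mismatch cap; 150 bp reads at ~1% error rarely exceed it. |
| `merge_window` | 10 bp | junction consolidation distance; junctions from both tag sides and staggered joining land within a few bases. |
| `flank` | 25 bp | scan half-window around a consolidated site; junction scatter plus frame length. |
| `max_mismatches` | 7 | combined protospacer+PAM budget. |
| `min_replicates` | 2 | biological replicates required for high confidence. |
| `low_read_threshold` | 10 reads | calls below it carry a flag (variable reproducibility at low depth) instead of being dropped. |

Two behavioural decisions worth stating explicitly:

* **Low-read sites are flagged, not filtered.** Sites under 10 supporting
  reads reproduce variably across replicates, but discarding them would
  hide rare events; `low_read_flag` plus the replicate confidence class
  conveys the uncertainty.
* **Multi-mapping fragments are discarded**, never randomly placed: a
  random placement would fabricate off-target loci. Ambiguity is counted
  and logged.

## Coordinates, ties and degenerate inputs

All internal coordinates are 0-based, half-open; BED output keeps that
convention and human-readable TSVs are 1-based. The junction coordinate
of a site is the insertion point between the two genomic bases that
flanked the break, so left-side and right-side fragments of one blunt
integration resolve to the same number. Consolidation places a site at
its read-weighted modal junction with ties to the leftmost position.
Empty inputs flow through every stage (zero-call outputs, exit status 0);
an absent on-target call makes the off-index undefined and it is reported
as missing with an explanation rather than silently zero.

Truncated tags need care: when the tag appears reverse-complemented in a
read, the detected anchor sits at the far end of the integrated piece,
and naively assuming a full-length tag would swallow genomic bases and
shift the junction by up to `taglen - truncation`. The splitter therefore
extends the actual tag match outward from the anchor (tolerating one
internal mismatch, never counting a trailing one) and cuts at the last
confirmed tag base. One consequence remains: a genomic base that
coincidentally continues the tag pattern is indistinguishable from tag
sequence, so single-base junction shifts are possible; the consolidation
window absorbs them.

## What the simulator emulates — and what it does not

`simulate_genome()` draws a uniform ACGT background (default 100 kb),
plants the exact on-target frame once and each planned off-target frame
with exactly its declared mismatch count (mismatches confined to the
protospacer, PAM kept pattern-valid) at positions ≥1 kb apart on
alternating strands. `simulate_discovery_library()` then cuts molecules
at each frame's implied blunt cut, inserts the tag in random orientation
(truncated or tandem at configured probabilities, tandem capped at the
low observed 0–10% range), shears to 500–700 bp, attaches barcode and
UMI, emits 150 bp pairs and applies uniform substitution error. PCR
duplicates are modelled as extra reads sharing a molecule's UMI. Untagged
background fragments (default half of all reads) exercise tag-detection
specificity.

Three generator choices are deliberate idealizations:

* the junction is placed 30–90 bp from the sequenced fragment end so it
  falls within read 1 — the real enrichment PCR achieves this selection
  chemically; reads whose junction lies beyond read 1 exist in real data
  and are simply uninformative there;
* UMIs are drawn without replacement within a site: with 4^8 = 65,536
  possible UMIs and tens of molecules per site, collisions are rare in
  reality and zero in the generator, which makes molecule-count recovery
  exact and testable;
* amplicon reference sequences are drawn free of near-matches to the tag
  (`simulate_amplicon_reference()`), mirroring assay design; a reference
  sharing a ≥10-nt block with the tag within one mismatch would make
  unedited reads indistinguishable from edited ones, and
  `amplicon_spec()` warns in that case.

Not modelled: chromatin effects on cleavage, junction microhomology,
PCR-bias and quality-score error profiles, indel-bearing (non-tag)
repair outcomes. Passing tests on simulated data therefore demonstrate
the correctness of the computational rules, not the biological
completeness of the assay.

## Amplicon insertion outcomes

For targeted amplicons (200–280 bp typical), reads bearing the target
anchor are split by tag detection (any ≥10-nt tag block within one
mismatch, either orientation). Insertion-bearing reads are classified by
their length excess over the reference: for the 34-nt tag, an excess of
29–49 bp is a single insertion and 64–84 bp a double; for the 39-nt tag
the windows are 34–54 and 69–89 (inclusive bounds; windows for other tag
lengths are supplied explicitly). Reads with an insertion but an
out-of-window excess form the explicit `edited_other` class, which makes
the partition exhaustive and keeps truncation-heavy samples visible. The
insertion frequency sums only single- and double-insertion reads over
target reads; the full-length rate divides complete-oligo reads by all
insertion-bearing reads including truncated ones. Length classification
presupposes a read spanning the amplicon: spanning single reads are used
directly and `merge_read_pair()` (exact overlap ≥20 bp, ≤2 mismatches)
reconstructs spans from overlapping pairs — note that 150 bp pairs cannot
span a >300 bp double-insertion product, which is why the quantification
path takes merged or long reads as input.

## Problem sizes and verification

The shipped tests and the acceptance script run entirely on simulated
data at desk scale, chosen to finish in minutes while leaving the
statistics meaningful: 100 kb genomes with 21 planted sites (mismatch
counts 1–7, ≥10 molecules each, 0.5% substitution error) for end-to-end
recovery; 500 random instances for scanner/oracle equivalence; 200
fragments against a full-genome Hamming oracle for the aligner; and
2,000-read amplicon pools (60/25/10/5% class fractions, 70% full-length)
recovered within three-sigma binomial tolerance. Real discovery datasets
(human genome, hundreds of off-target sites) run through the same module
surfaces with an external aligner via the SAM ingestion path.

## Known limitations

* Ungapped alignment only: indels near a junction are handled by seed
  fallback, not modelled; production-scale genomes should use the
  external-SAM path.
* No bulge/gap off-target matching.
* UMI deduplication is exact-identity; Hamming-1 UMI merging is a noted
  possible extension.
* No statistical background model: site nomination is rule-based, and no
  multiple-testing machinery applies.
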