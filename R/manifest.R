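## default tunable parameters, all overridable from the manifest `params:`
## block; ranges enforced by validate_manifest()
default_params <- function() {
  list(
    max_barcode_mm = 1L,      # barcode Hamming tolerance
    umi_length = 8L,          # adaptor molecular index length
    max_anchor_mm = 1L,       # tag anchor tolerance
    max_full_mm = 1L,         # full-length tag tolerance
    min_fragment_length = 25L,# smallest aligned junction fragment
    k = 20L,                  # aligner seed length
    max_align_mm = 3L,        # per-fragment alignment mismatch cap
    merge_window = 10L,       # junction consolidation distance
    flank = 25L,              # protospacer scan half-window
    max_mismatches = 7L,      # combined protospacer+PAM budget
    min_replicates = 2L,      # replicates for high confidence
    locus_tolerance = 10L,    # cross-replicate locus grouping distance
    low_read_threshold = 10L  # read support below which calls are flagged
  )
}

param_ranges <- function() {
  list(
    max_barcode_mm = c(0L, 3L), umi_length = c(4L, 16L),
    max_anchor_mm = c(0L, 3L), max_full_mm = c(0L, 3L),
    min_fragment_length = c(20L, 100L), k = c(12L, 32L),
    max_align_mm = c(0L, 10L), merge_window = c(0L, 100L),
    flank = c(5L, 200L), max_mismatches = c(0L, 15L),
    min_replicates = c(1L, 10L), locus_tolerance = c(0L, 100L),
    low_read_threshold = c(0L, 1000L)
  )
}

#' Validate a run manifest
#'
#' Parses and validates the YAML manifest driving a run: samples with
#' unique, equal-length barcodes and non-empty replicate groups; guide and
#' dsODN definitions; existing input paths (unless a `simulate:` block will
#' generate them); parameters within documented ranges; unknown keys
#' rejected. All problems are reported in one error.
#'
#' @param manifest path to a YAML file, or an equivalent list.
#' @return a validated `run_manifest` list with defaults filled in.
#' @export
validate_manifest <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- yaml::read_yaml(manifest)
  }
  errs <- character()
  known <- c("reference", "output_dir", "barcode_mate", "samples", "guides",
             "dsodns", "amplicons", "params", "simulate", "seed")
  unknown <- setdiff(names(manifest), known)
  if (length(unknown)) {
    errs <- c(errs, paste("unknown manifest keys:", paste(unknown, collapse = ", ")))
  }
  simulated <- !is.null(manifest$simulate)

  for (key in c("samples", "guides", "dsodns")) {
    if (is.null(manifest[[key]]) || !length(manifest[[key]])) {
      errs <- c(errs, paste("missing required key:", key))
    }
  }
  if (!simulated && is.null(manifest$reference)) {
    errs <- c(errs, "missing required key: reference (no simulate block)")
  }
  if (!simulated && !is.null(manifest$reference) &&
      !file.exists(manifest$reference)) {
    errs <- c(errs, paste("reference file not found:", manifest$reference))
  }

  samples <- manifest$samples
  if (length(samples)) {
    ids <- vapply(samples, function(s) s$id %||% NA_character_, character(1L))
    bcs <- vapply(samples, function(s) s$barcode %||% NA_character_, character(1L))
    grp <- vapply(samples, function(s) s$replicate_group %||% "", character(1L))
    if (anyNA(ids)) errs <- c(errs, "every sample needs an id")
    if (anyNA(bcs)) {
      errs <- c(errs, "every sample needs a barcode")
    } else {
      dup <- bcs[duplicated(bcs)]
      for (d in unique(dup)) {
        errs <- c(errs, sprintf("samples %s share barcode %s",
                                paste(ids[bcs == d], collapse = ", "), d))
      }
      if (length(unique(nchar(bcs))) > 1L) {
        errs <- c(errs, "barcodes must all have equal length")
      }
    }
    if (any(!nzchar(grp))) {
      errs <- c(errs, sprintf("samples missing replicate_group: %s",
                              paste(ids[!nzchar(grp)], collapse = ", ")))
    }
    if (!simulated) {
      for (s in samples) {
        for (f in c("r1", "r2")) {
          if (is.null(s[[f]]) || !file.exists(s[[f]])) {
            errs <- c(errs, sprintf("sample %s: %s file missing (%s)",
                                    s$id %||% "?", f, s[[f]] %||% "unset"))
          }
        }
      }
    }
  }

  params <- utils::modifyList(default_params(), manifest$params %||% list())
  unknown_p <- setdiff(names(params), names(default_params()))
  if (length(unknown_p)) {
    errs <- c(errs, paste("unknown params:", paste(unknown_p, collapse = ", ")))
  }
  rng <- param_ranges()
  for (p in intersect(names(params), names(rng))) {
    v <- params[[p]]
    if (!is.numeric(v) || v < rng[[p]][1L] || v > rng[[p]][2L]) {
      errs <- c(errs, sprintf("param %s = %s out of range [%d, %d]",
                              p, as.character(v), rng[[p]][1L], rng[[p]][2L]))
    }
  }

  guides <- lapply(manifest$guides, function(g) {
    tryCatch(
      {
        gs <- guide_spec(g$name, g$protospacer, g$pam %||% "NGG",
                         g$cut_offset %||% 3L)
        gs$on_target <- g$on_target  # optional intended-cut locus
        gs
      },
      error = function(e) {
        errs <<- c(errs, sprintf("guide %s: %s", g$name %||% "?",
                                 conditionMessage(e)))
        NULL
      }
    )
  })
  dsodns <- lapply(manifest$dsodns, function(d) {
    tryCatch(
      dsodn_spec(d$name, d$sequence, d$anchor_length %||% 12L),
      error = function(e) {
        errs <<- c(errs, sprintf("dsodn %s: %s", d$name %||% "?",
                                 conditionMessage(e)))
        NULL
      }
    )
  })

  if (length(errs)) {
    stop("invalid manifest:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  names(guides) <- vapply(guides, `[[`, character(1L), "name")
  names(dsodns) <- vapply(dsodns, `[[`, character(1L), "name")

  structure(list(
    reference = manifest$reference,
    output_dir = manifest$output_dir %||% "breaktag_out",
    barcode_mate = manifest$barcode_mate %||% "R1",
    samples = samples,
    guides = guides,
    dsodns = dsodns,
    amplicons = manifest$amplicons,
    params = lapply(params, function(x) if (is.numeric(x)) as.integer(x) else x),
    simulate = manifest$simulate,
    seed = manifest$seed %||% 1L
  ), class = "run_manifest")
}

log_line <- function(con, ..., quiet = FALSE) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  if (!quiet) message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full discovery pipeline from a manifest
#'
#' Orchestrates demultiplexing, UMI extraction, tag scanning, alignment,
#' junction consolidation, off-target calling, replicate confidence
#' classification and the off-index, writing per-stage TSVs, a sites BED,
#' a rendered site table and a log with per-stage conservation counts
#' under `output_dir`. When the manifest carries a `simulate:` block the
#' reference and per-sample FASTQs are generated first (deterministically
#' from the manifest seed). Reruns with identical manifest and seed
#' produce byte-identical call tables.
#'
#' @param manifest a path, list, or validated `run_manifest`.
#' @param output_dir overrides the manifest output directory.
#' @param seed overrides the manifest seed.
#' @param quiet suppress console log lines (the log file is always
#'   written).
#' @return invisibly, a list: per-sample `calls`, `off_index`, per-group
#'   `confidence`, the demux `report`, and `output_dir`.
#' @export
run_pipeline <- function(manifest, output_dir = NULL, seed = NULL,
                         quiet = FALSE) {
  if (!inherits(manifest, "run_manifest")) {
    manifest <- validate_manifest(manifest)
  }
  if (!is.null(output_dir)) manifest$output_dir <- output_dir
  if (!is.null(seed)) manifest$seed <- seed
  out <- manifest$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  p <- manifest$params
  log_line(logf, "run starting; seed = ", manifest$seed, quiet = quiet)
  log_line(logf, "effective parameters: ",
           paste(names(p), unlist(p), sep = "=", collapse = " "),
           quiet = quiet)

  ## --- optional simulation stage -------------------------------------
  if (!is.null(manifest$simulate)) {
    manifest <- simulate_inputs(manifest, logf, quiet)
  }

  index <- build_index(manifest$reference, k = p$k)
  reference <- index$seqs
  log_line(logf, "reference indexed: ", length(reference), " contig(s), k = ",
           p$k, quiet = quiet)

  sample_dt <- data.table(
    sample_id = vapply(manifest$samples, `[[`, character(1L), "id"),
    barcode = vapply(manifest$samples, `[[`, character(1L), "barcode"),
    r1 = vapply(manifest$samples, `[[`, character(1L), "r1"),
    r2 = vapply(manifest$samples, `[[`, character(1L), "r2"),
    guide = vapply(manifest$samples, `[[`, character(1L), "guide"),
    dsodn = vapply(manifest$samples, `[[`, character(1L), "dsodn"),
    replicate_group = vapply(manifest$samples, `[[`, character(1L),
                             "replicate_group")
  )

  all_calls <- list()
  off_index <- list()
  demux_reports <- list()

  ## samples sharing a FASTQ pair are demultiplexed together
  for (grp in split(seq_len(nrow(sample_dt)),
                    paste(sample_dt$r1, sample_dt$r2))) {
    sub <- sample_dt[grp]
    pairs <- read_fastq_pairs(sub$r1[1L], sub$r2[1L])
    dmx <- demultiplex(pairs, sub[, .(sample_id, barcode)],
                       max_barcode_mm = p$max_barcode_mm,
                       barcode_mate = manifest$barcode_mate)
    demux_reports[[length(demux_reports) + 1L]] <- dmx$report
    log_line(logf, "demux ", sub$r1[1L], ": ", nrow(pairs), " pairs in = ",
             sum(dmx$report$n_assigned), " assigned+unassigned out",
             quiet = quiet)

    for (i in seq_len(nrow(sub))) {
      sid <- sub$sample_id[i]
      sdir <- file.path(out, sid)
      dir.create(sdir, showWarnings = FALSE)
      guide <- manifest$guides[[sub$guide[i]]]
      dsodn <- manifest$dsodns[[sub$dsodn[i]]]
      if (is.null(guide)) stop("sample ", sid, ": unknown guide ", sub$guide[i])
      if (is.null(dsodn)) stop("sample ", sid, ": unknown dsodn ", sub$dsodn[i])

      um <- extract_umi(dmx$samples[[sid]], umi_length = p$umi_length,
                        umi_mate = manifest$barcode_mate)
      reads <- um$reads
      log_line(logf, sid, ": ", nrow(dmx$samples[[sid]]), " assigned = ",
               nrow(reads), " with UMI + ", um$n_dropped, " dropped",
               quiet = quiet)

      hits <- find_tag(reads$seq1, dsodn, max_anchor_mm = p$max_anchor_mm,
                       max_full_mm = p$max_full_mm)
      tagscan <- cbind(data.table(read_id = reads$read_id), hits)
      fwrite(tagscan, file.path(sdir, "tagscan.tsv"), sep = "\t")
      log_line(logf, sid, ": ", sum(hits$found), " tag-bearing of ",
               nrow(reads), " reads", quiet = quiet)

      frags <- split_at_junction(reads, hits, dsodn,
                                 min_fragment_length = p$min_fragment_length)
      aln <- align_fragments(frags, index, max_mm = p$max_align_mm)
      log_line(logf, sid, ": ", nrow(frags), " fragments in = ",
               nrow(aln$junctions), " aligned + ", aln$n_unaligned,
               " unaligned + ", aln$n_ambiguous, " ambiguous", quiet = quiet)
      fwrite(aln$junctions, file.path(sdir, "junctions.tsv"), sep = "\t")

      sites <- consolidate(aln$junctions, merge_window = p$merge_window)
      write_sites_bed(sites, file.path(sdir, "sites.bed"))

      on_target <- manifest$guides[[sub$guide[i]]]$on_target
      cs <- call_sites(sites, guide, reference, flank = p$flank,
                       max_mismatches = p$max_mismatches,
                       on_target = on_target,
                       low_read_threshold = p$low_read_threshold)
      log_line(logf, sid, ": ", nrow(sites), " sites in = ", nrow(cs$calls),
               " calls + ", cs$n_dropped, " dropped (no frame within ",
               p$max_mismatches, " mismatches)", quiet = quiet)
      write_calls_tsv(cs$calls, file.path(sdir, "calls.tsv"))
      writeLines(render_site_table(cs$calls, guide, "text"),
                 file.path(sdir, "calls_table.txt"))

      oi <- compute_off_index(cs$calls)
      fwrite(data.table(sample_id = sid,
                        off_reads_total = oi$off_reads_total,
                        on_reads = oi$on_reads, value = oi$value),
             file.path(sdir, "offindex.tsv"), sep = "\t")
      all_calls[[sid]] <- cs$calls
      off_index[[sid]] <- oi
    }
  }

  ## --- replicate confidence per group --------------------------------
  confidence <- list()
  for (g in unique(sample_dt$replicate_group)) {
    members <- sample_dt[replicate_group == g, sample_id]
    conf <- classify_confidence(all_calls[members],
                                min_replicates = p$min_replicates,
                                locus_tolerance = p$locus_tolerance)
    fwrite(conf, file.path(out, paste0("confidence_", g, ".tsv")), sep = "\t")
    confidence[[g]] <- conf
    log_line(logf, "group ", g, ": ", nrow(conf), " loci, ",
             sum(conf$confidence == "high"), " high-confidence",
             quiet = quiet)
  }
  report <- rbindlist(demux_reports)
  fwrite(report, file.path(out, "demux_report.tsv"), sep = "\t")
  log_line(logf, "run complete", quiet = quiet)
  invisible(list(calls = all_calls, off_index = off_index,
                 confidence = confidence, report = report,
                 output_dir = out))
}

## generate reference + per-sample FASTQs from the manifest simulate block
simulate_inputs <- function(manifest, logf, quiet) {
  sb <- manifest$simulate
  out <- manifest$output_dir
  guide <- manifest$guides[[sb$guide %||% names(manifest$guides)[1L]]]
  dsodn <- manifest$dsodns[[sb$dsodn %||% names(manifest$dsodns)[1L]]]
  cfg_args <- sb[setdiff(names(sb), c("guide", "dsodn"))]
  cfg_args$seed <- cfg_args$seed %||% manifest$seed
  if (!is.null(cfg_args$offtarget_plan)) {
    cfg_args$offtarget_plan <- rbindlist(lapply(cfg_args$offtarget_plan,
                                                as.data.table))
  }
  cfg <- do.call(sim_config, c(list(guide = guide, dsodn = dsodn), cfg_args))

  sim <- simulate_genome(cfg)
  ref_path <- file.path(out, "reference_sim.fa")
  write_genome_fasta(sim, ref_path)
  manifest$reference <- ref_path
  ## intended cut locus for on-target identification
  manifest$guides[[guide$name]]$on_target <-
    list(seq_name = sim$truth$seq_name[1L],
         position = sim$truth$cut_pos[1L])
  log_line(logf, "simulated genome: ", nchar(sim$genome[[1L]]), " bp, ",
           nrow(sim$truth), " planted sites", quiet = quiet)

  for (i in seq_along(manifest$samples)) {
    s <- manifest$samples[[i]]
    cfg_i <- cfg
    cfg_i$barcode <- s$barcode
    sim_i <- sim
    sim_i$cfg <- cfg_i
    lib <- simulate_discovery_library(sim_i, seed = cfg$seed + i)
    r1 <- file.path(out, paste0(s$id, "_R1.fastq.gz"))
    r2 <- file.path(out, paste0(s$id, "_R2.fastq.gz"))
    write_fastq_pairs(lib$pairs, r1, r2)
    fwrite(lib$truth_reads, file.path(out, paste0(s$id, "_truth.tsv")),
           sep = "\t")
    manifest$samples[[i]]$r1 <- r1
    manifest$samples[[i]]$r2 <- r2
    log_line(logf, "simulated ", s$id, ": ", nrow(lib$pairs), " read pairs (",
             lib$n_tagged_reads, " tagged + ", lib$n_background,
             " background)", quiet = quiet)
  }
  manifest
}

#' Write consolidated sites as BED
#'
#' 0-based half-open intervals; the BED score column carries the read
#' count.
#'
#' @param sites site table from [consolidate()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.table(
    chrom = sites$seq_name, start = sites$window_start,
    end = sites$window_end,
    name = sprintf("site_%d", seq_len(nrow(sites))),
    score = sites$read_count, strand = "."
  )
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write annotated calls as TSV (1-based inclusive coordinates)
#'
#' @param calls calls table from [call_sites()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- data.table(
    contig = calls$seq_name,
    start = calls$position + 1L,
    end = calls$position + 1L,
    strand = calls$target_strand,
    matched_seq = calls$matched_seq,
    mismatch_count = calls$mismatch_count,
    mismatch_positions = calls$mismatch_positions,
    read_count = calls$read_count,
    umi_count = calls$umi_count,
    side_left = calls$side_left,
    side_right = calls$side_right,
    is_on_target = calls$is_on_target,
    low_read_flag = calls$low_read_flag
  )
  fwrite(out, path, sep = "\t")
  invisible(path)
}
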