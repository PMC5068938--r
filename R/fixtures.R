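# Seeded synthetic-sequence generator: genomes/CDS sets and target
# transcripts with planted PAS-compliant sites and exact truth tables, so
# every pipeline stage is testable without external data.

random_chars <- function(n, gc_fraction = 0.4, alphabet = DNA_BASES) {
  at <- (1 - gc_fraction) / 2
  gc <- gc_fraction / 2
  sample(alphabet, n, replace = TRUE, prob = c(at, gc, gc, at))
}

mismatch_base_for <- function(handle_b, config) {
  setdiff(RNA_BASES, paired_target_bases(handle_b, config))
}

# A planted PAS (full Watson-Crick complement of the handle) can force
# frame-shifted neighbour windows to pass when the handle pairs its own
# complement under a shift: those "automatic" pairs sit on protected planted
# bases and no background scrub can remove them. Returns the worst-case
# automatic paired count over all shifts 1..7 in both directions.
handle_shift_autopairs <- function(handle, config) {
  comp <- vapply(1:8, function(j) WC_PARTNER[[handle_base(handle, j)]], "")
  worst <- 0L
  for (d in 1:7) {
    right <- sum(vapply(seq_len(8L - d), function(i) {
      cls <- classify_pair(comp[d + i], handle_base(handle, i))
      cls == "WATSON_CRICK" ||
        (config$wobble_counts_as_paired && cls == "WOBBLE")
    }, TRUE))
    left <- sum(vapply(seq_len(8L - d), function(i) {
      cls <- classify_pair(comp[i], handle_base(handle, i + d))
      cls == "WATSON_CRICK" ||
        (config$wobble_counts_as_paired && cls == "WOBBLE")
    }, TRUE))
    worst <- max(worst, right, left)
  }
  worst
}

#' Synthesise a target transcript with planted protospacer sites
#'
#' Generates a random mRNA carrying exactly `k_sites` fully PAS-compliant
#' protospacer windows (all 8 handle positions Watson-Crick paired) at
#' recorded positions. The background is scrubbed of accidental windows
#' that would pass the full criterion (`min_paired` of the config), by
#' resampling the minimally disrupting PAS base, so a scan recovers exactly
#' the planted truth. Deterministic for a fixed seed.
#'
#' @param length transcript length in nt (default 2709, a realistic
#'   single-gene mRNA scale).
#' @param k_sites number of planted sites.
#' @param handle a [handle_spec()].
#' @param protospacer_length protospacer window length (default 37).
#' @param seed RNG seed.
#' @param config [pas_config()] defining the criterion the background must
#'   not pass.
#' @param gc_fraction background GC content.
#' @param id transcript id.
#' @param max_scrub_rounds scrub-iteration budget.
#' @return list with `transcript` (RNA [nuc_seq()]) and `truth` (class
#'   `fixture_truth`: `planted_protospacers` data.frame, `rng_seed`,
#'   `generation_params`).
#' @export
synth_target_transcript <- function(length = 2709L, k_sites, handle,
                                    protospacer_length = 37L, seed = 1L,
                                    config = pas_config(),
                                    gc_fraction = 0.4,
                                    id = "synthetic_target",
                                    max_scrub_rounds = 200L) {
  length <- as.integer(length); k_sites <- as.integer(k_sites)
  L <- as.integer(protospacer_length)
  foot <- L + 8L
  if (k_sites > 0L && length < k_sites * (foot + 4L)) {
    mc_error(sprintf(
      "length %d cannot accommodate %d sites of %d nt with separation",
      length, k_sites, foot), "minicr_packing_error")
  }
  if (k_sites > 0L) {
    auto <- handle_shift_autopairs(handle, config)
    if (auto >= config$min_paired) {
      mc_error(sprintf(
        "handle %s pairs its own complement at %d positions under a frame shift (criterion needs %d): planted sites would spawn unscrubable neighbour windows; choose a less self-complementary handle",
        handle$handle_rna, auto, config$min_paired), "minicr_handle_error")
    }
  }
  with_seed(seed, {
    for (attempt in 1:20) {
      out <- try(synth_target_once(length, k_sites, handle, L, foot, config,
                                   gc_fraction, max_scrub_rounds),
                 silent = TRUE)
      if (!inherits(out, "try-error")) break
      if (attempt == 20L) {
        mc_error("could not scrub a compliant background in 20 attempts",
                 "minicr_packing_error")
      }
    }
    truth <- structure(list(
      planted_protospacers = data.frame(
        transcript_id = rep(id, k_sites),
        start = sort(out$starts), length = rep(L, k_sites),
        stringsAsFactors = FALSE),
      rng_seed = seed,
      generation_params = list(length = length, k_sites = k_sites,
                               handle_rna = handle$handle_rna,
                               protospacer_length = L,
                               gc_fraction = gc_fraction,
                               min_paired = config$min_paired,
                               wobble_counts_as_paired =
                                 config$wobble_counts_as_paired)),
      class = "fixture_truth")
    list(transcript = nuc_seq(id, paste(out$chars, collapse = ""),
                              alphabet = "RNA"),
         truth = truth)
  })
}

# one generation attempt; signals a packing error when the scrub dead-ends
synth_target_once <- function(length, k_sites, handle, L, foot, config,
                              gc_fraction, max_scrub_rounds) {
  {
    chars <- random_chars(length, gc_fraction, RNA_BASES)
    starts <- integer(0)
    if (k_sites > 0L) {
      # one site per equal-width block, uniformly placed within the block
      block <- length %/% k_sites
      starts <- vapply(seq_len(k_sites), function(i) {
        lo <- (i - 1L) * block + 1L
        hi <- i * block - foot + 1L
        if (hi < lo) mc_error("infeasible packing", "minicr_packing_error")
        sample(lo:hi, 1L)
      }, 0L)
      for (s in starts) {
        for (i in 1:8) {
          chars[s + L + i - 1L] <- WC_PARTNER[[handle_base(handle, i)]]
        }
      }
    }
    # only the planted PAS bases are load-bearing; the protospacer body may
    # be resampled freely during scrubbing
    planted_foot <- unlist(lapply(starts, function(s) (s + L):(s + L + 7L)))
    scfg <- scan_config(protospacer_length = L, criterion_mode = "full",
                        pas_config = config)
    for (round in seq_len(max_scrub_rounds)) {
      res <- scan_transcript(paste(chars, collapse = ""), handle, scfg)
      extra <- setdiff(res$start, starts)
      if (length(extra) == 0L) break
      fixed_any <- FALSE
      for (s in extra) {
        cand <- integer(0)
        for (i in 1:8) {
          p <- s + L + i - 1L
          cls <- classify_pair(chars[p], handle_base(handle, i))
          if (cls == "MISMATCH") next
          if (p %in% planted_foot) next
          cand <- c(cand, i)
        }
        if (length(cand) == 0L) next
        i <- if (length(cand) == 1L) cand else sample(cand, 1L)
        p <- s + L + i - 1L
        pool <- mismatch_base_for(handle_base(handle, i), config)
        chars[p] <- if (length(pool) == 1L) pool else sample(pool, 1L)
        fixed_any <- TRUE
      }
      if (!fixed_any) {
        mc_error("background scrub stuck: accidental site inside planted footprints",
                 "minicr_packing_error")
      }
      if (round == max_scrub_rounds) {
        mc_error("background scrub budget exhausted", "minicr_packing_error")
      }
    }
    list(chars = chars, starts = starts)
  }
}

# remove every occurrence of `patterns` (RNA 3-mers) from chars, never
# touching positions in `protected`; returns chars or NULL when stuck
scrub_motifs <- function(chars, patterns, protected = integer(0),
                         planted_pos = integer(0), budget = 200L) {
  n <- length(chars)
  if (n < 3L) return(chars)
  for (round in seq_len(budget)) {
    tri <- paste0(chars[1:(n - 2L)], chars[2:(n - 1L)], chars[3:n])
    occ <- setdiff(which(tri %in% patterns), planted_pos)
    if (length(occ) == 0L) return(chars)
    fixed_any <- FALSE
    for (p in occ) {
      free <- setdiff(p:(p + 2L), protected)
      if (length(free) == 0L) next
      q <- if (length(free) == 1L) free else sample(free, 1L)
      pool <- setdiff(RNA_BASES, chars[q])
      chars[q] <- sample(pool, 1L)
      fixed_any <- TRUE
    }
    if (!fixed_any) return(NULL)
  }
  NULL
}

#' Synthesise a genome of CDS with planted minimal PAS motifs
#'
#' Builds `n_cds` coding sequences whose minimal-motif occurrence counts are
#' exactly `planted_counts`: the background is scrubbed of accidental motif
#' hits (against the wobble-inclusive pattern set, so counts hold under
#' either wobble setting) and Watson-Crick-only motif trinucleotides are
#' planted at positions with full protospacer room upstream. CDS are placed
#' on alternating strands with random intergenic spacers and returned with
#' a matching annotation table.
#'
#' @param n_cds number of CDS.
#' @param length_range `c(min, max)` CDS length in nt.
#' @param gc_fraction background GC content.
#' @param planted_counts integer vector, one motif count per CDS.
#' @param seed RNG seed.
#' @param handle a [handle_spec()].
#' @param protospacer_length used for the upstream-room constraint.
#' @param genome_id genome record id.
#' @return list with `genome` (DNA [nuc_seq()]), `annotation` (data.frame),
#'   `cds` (list of `cds_record`), and `truth` (`fixture_truth` with
#'   `planted_motifs_per_cds`).
#' @export
synth_cds_set <- function(n_cds, length_range = c(400L, 1200L),
                          gc_fraction = 0.4, planted_counts, seed = 1L,
                          handle, protospacer_length = 37L,
                          genome_id = "synthetic_genome") {
  n_cds <- as.integer(n_cds)
  planted_counts <- as.integer(planted_counts)
  if (length(planted_counts) != n_cds) {
    mc_error("planted_counts must have one entry per CDS",
             "minicr_input_error")
  }
  L <- as.integer(protospacer_length)
  patterns_any <- minimal_motif_patterns(
    handle, pas_config(wobble_counts_as_paired = TRUE))
  patterns_wc <- minimal_motif_patterns(
    handle, pas_config(wobble_counts_as_paired = FALSE))
  if (length(patterns_wc) == 0L) {
    mc_error("handle admits no Watson-Crick-only minimal motif",
             "minicr_input_error")
  }
  with_seed(seed, {
    tags <- sprintf("SYN_%04d", seq_len(n_cds))
    mrnas <- vector("list", n_cds)
    for (ci in seq_len(n_cds)) {
      len <- sample(length_range[1]:length_range[2], 1L)
      k <- planted_counts[ci]
      min_pos <- L + 3L
      if (k > 0L && (len - 2L - min_pos) < (k - 1L) * 5L) {
        mc_error(sprintf(
          "CDS %s (%d nt) cannot hold %d motif sites with upstream room",
          tags[ci], len, k), "minicr_packing_error")
      }
      chars <- random_chars(len, gc_fraction, RNA_BASES)
      chars <- scrub_motifs(chars, patterns_any)
      if (is.null(chars)) {
        mc_error("motif scrub failed", "minicr_packing_error")
      }
      planted <- integer(0)
      if (k > 0L) {
        # k sites, >= 5 nt apart, all with upstream room
        slots <- seq(min_pos, len - 2L, by = 5L)
        planted <- sort(sample(slots, k))
        for (p in planted) {
          pat <- sample(patterns_wc, 1L)
          chars[p:(p + 2L)] <- strsplit(pat, "")[[1]]
        }
        chars <- scrub_motifs(chars, patterns_any,
                              protected = unlist(lapply(planted, function(p)
                                p:(p + 2L))),
                              planted_pos = planted)
        if (is.null(chars)) {
          mc_error("motif scrub failed after planting",
                   "minicr_packing_error")
        }
      }
      mrnas[[ci]] <- paste(chars, collapse = "")
    }
    # lay CDS on the genome with random intergenic spacers
    genome_parts <- character(0)
    ann <- list()
    pos <- 0L
    for (ci in seq_len(n_cds)) {
      inter <- paste(random_chars(sample(50:150, 1L), gc_fraction), collapse = "")
      genome_parts <- c(genome_parts, inter)
      pos <- pos + nchar(inter)
      strand <- if (ci %% 2L == 1L) "+" else "-"
      dna <- rna_to_dna(mrnas[[ci]])
      seg <- if (strand == "+") dna else revcomp_chr(dna, "DNA")
      genome_parts <- c(genome_parts, seg)
      ann[[ci]] <- data.frame(locus_tag = tags[ci], start = pos + 1L,
                              end = pos + nchar(seg), strand = strand,
                              stringsAsFactors = FALSE)
      pos <- pos + nchar(seg)
    }
    genome_parts <- c(genome_parts,
                      paste(random_chars(sample(50:150, 1L), gc_fraction),
                            collapse = ""))
    genome <- nuc_seq(genome_id, paste(genome_parts, collapse = ""),
                      alphabet = "DNA")
    annotation <- do.call(rbind, ann)
    truth <- structure(list(
      planted_motifs_per_cds = stats::setNames(planted_counts, tags),
      rng_seed = seed,
      generation_params = list(n_cds = n_cds, length_range = length_range,
                               gc_fraction = gc_fraction,
                               handle_rna = handle$handle_rna,
                               protospacer_length = L)),
      class = "fixture_truth")
    list(genome = genome, annotation = annotation,
         cds = extract_cds(genome, annotation), truth = truth)
  })
}

#' Synthesise a miniCRISPR backbone
#'
#' Random leader, repeat and backbone spacers for worked examples and
#' simulation tests (labelled synthetic; natural backbones are supplied via
#' the configuration file).
#'
#' @param seed RNG seed.
#' @param n_spacers number of backbone spacers (named D1, D2, ...).
#' @param spacer_length backbone spacer length in nt.
#' @param repeat_length repeat length in nt.
#' @param leader_length leader length in nt (default 497).
#' @param gc_fraction GC content.
#' @return a [minicr_backbone()].
#' @export
synth_backbone <- function(seed = 1L, n_spacers = 6L, spacer_length = 37L,
                           repeat_length = 24L, leader_length = 497L,
                           gc_fraction = 0.4) {
  with_seed(seed, {
    leader <- paste(random_chars(leader_length, gc_fraction), collapse = "")
    rep_seq <- paste(random_chars(repeat_length, gc_fraction), collapse = "")
    spacers <- vapply(seq_len(n_spacers), function(i)
      paste(random_chars(spacer_length, gc_fraction), collapse = ""), "")
    names(spacers) <- paste0("D", seq_len(n_spacers))
    minicr_backbone(leader, rep_seq, spacers)
  })
}

#' Write a synthetic CDS fixture set to disk
#'
#' FASTA genome + GFF3 annotation + JSON truth file.
#'
#' @param fixture result of [synth_cds_set()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_fixture_set <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "annotation.gff3")
  truth <- file.path(dir, "truth.json")
  write_fasta(fixture$genome, fa)
  write_gff3_cds(fixture$annotation, fixture$genome$id, gff)
  jsonlite::write_json(
    list(planted_motifs_per_cds =
           as.list(fixture$truth$planted_motifs_per_cds),
         rng_seed = fixture$truth$rng_seed,
         generation_params = fixture$truth$generation_params),
    truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(genome = fa, annotation = gff, truth = truth)
}
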