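# Modular overlap-extension PCR (OE-PCR): design of flank, MOE and M primer
# sets, in-silico fusion into an OE fragment, megaprimer insertion into a
# circular template, and the inverse-PCR dosage route for repeated spacers.
#
# Simulation model: annealing is exact string matching of a primer's
# 3'-terminal region (no melting-temperature model), which keeps every
# simulated step deterministic and makes failures attributable.

MIN_PRIMER_LENGTH <- 15L

new_primer <- function(name, seq, role) {
  seq <- toupper(seq)
  check_alphabet(seq, "DNA", name)
  if (nchar(seq) < MIN_PRIMER_LENGTH) {
    mc_error(sprintf("primer '%s' is %d nt; minimum is %d nt",
                     name, nchar(seq), MIN_PRIMER_LENGTH),
             "minicr_primer_error")
  }
  structure(list(name = name, seq = seq, role = role), class = "mc_primer")
}

#' @export
print.mc_primer <- function(x, ...) {
  cat(sprintf("<primer> %s (%s, %d nt) 5'-%s-3'\n", x$name, x$role,
              nchar(x$seq), x$seq))
  invisible(x)
}

new_flank_unit <- function(left_spacer, right_spacer, fw, rv, product,
                           left_label = left_spacer,
                           right_label = right_spacer) {
  structure(list(left_spacer = left_spacer, right_spacer = right_spacer,
                 left_label = left_label, right_label = right_label,
                 fw_primer = fw, rv_primer = rv, product = product),
            class = "flank_unit")
}

#' @export
print.flank_unit <- function(x, ...) {
  cat(sprintf("<flank_unit> %s | repeat | %s (product %d nt)\n",
              x$left_label, x$right_label, nchar(x$product)))
  invisible(x)
}

#' Design one flank unit
#'
#' A flank is the elementary OE-PCR product: `left_spacer + repeat +
#' right_spacer`, produced by two primers that anneal on the repeat and are
#' extended from the middle of the flank. The two primers' repeat portions
#' overlap by `overlap` nt centred on the repeat midpoint; each primer also
#' carries one spacer — the unique part of the flank used for specific
#' fusion.
#'
#' @param left_spacer,right_spacer DNA spacers flanking the repeat.
#' @param repeat_seq DNA repeat.
#' @param overlap primer-primer overlap on the repeat (nt, default 12).
#' @param names optional `c(left, right)` labels used in primer names.
#' @return a `flank_unit` with `fw_primer`, `rv_primer`, `product`.
#' @export
design_flank_unit <- function(left_spacer, repeat_seq, right_spacer,
                              overlap = 12L, names = NULL) {
  left_spacer <- toupper(left_spacer); right_spacer <- toupper(right_spacer)
  repeat_seq <- toupper(repeat_seq)
  overlap <- as.integer(overlap)
  r <- nchar(repeat_seq)
  if (overlap > r) {
    mc_error(sprintf("overlap %d nt exceeds repeat length %d nt", overlap, r),
             "minicr_primer_error")
  }
  if (identical(left_spacer, repeat_seq) || identical(right_spacer, repeat_seq)) {
    mc_error("spacers must be distinct from the repeat",
             "minicr_primer_error")
  }
  a <- (r + overlap) %/% 2L           # fw primer's repeat portion
  b <- r + overlap - a                # rv primer's repeat portion
  lab <- if (is.null(names)) c("L", "R") else names
  fw <- new_primer(sprintf("flank_%s_%s_fw", lab[1], lab[2]),
                   paste0(left_spacer, substr(repeat_seq, 1L, a)),
                   "flank_fw")
  rv <- new_primer(sprintf("flank_%s_%s_rv", lab[1], lab[2]),
                   revcomp_chr(paste0(substr(repeat_seq, r - b + 1L, r),
                                      right_spacer), "DNA"),
                   "flank_rv")
  product <- paste0(left_spacer, repeat_seq, right_spacer)
  ext <- simulate_primer_extension(fw, rv)
  if (!identical(ext, product)) {
    mc_error("flank primer pair does not extend to the declared product",
             "minicr_simulation_error")
  }
  new_flank_unit(left_spacer, right_spacer, fw, rv, product,
                 left_label = lab[1], right_label = lab[2])
}

# two overlapping primers prime each other: the fw 3' end must anneal to
# the rv primer's template strand; the filled-in duplex is returned
simulate_primer_extension <- function(fw, rv, min_anneal = 12L) {
  top_rv <- revcomp_chr(rv$seq, "DNA")     # rv primer on the top strand
  fw3 <- substr(fw$seq, nchar(fw$seq) - min_anneal + 1L, nchar(fw$seq))
  hit <- find_all(top_rv, fw3)
  if (length(hit) != 1L) {
    mc_error(sprintf(
      "primer extension failed: 3' end of '%s' anneals %d time(s) on '%s'",
      fw$name, length(hit), rv$name), "minicr_simulation_error")
  }
  paste0(substr(fw$seq, 1L, nchar(fw$seq) - min_anneal),
         substr(top_rv, hit, nchar(top_rv)))
}

find_all <- function(subject, pattern) {
  if (!nzchar(pattern)) return(integer(0))
  out <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (out[1] == -1L) integer(0) else as.integer(out)
}

#' Design the MOE primers and terminal flank units
#'
#' The MOE primers tie the new spacers to the backbone: `moe_fw` is the
#' 3'-terminal arm of the first retained backbone spacer (by default D1)
#' followed by the repeat; `moe_rv` is the reverse complement of the repeat
#' followed by the 5' arm of the downstream retained spacer (D5). Each is
#' `total_length` nt; the arm length is `total_length` minus the repeat
#' length unless given. The terminal flank units pair each MOE primer with
#' the first/last new spacer.
#'
#' @param backbone a [minicr_backbone()].
#' @param first_new_spacer,last_new_spacer DNA of the first and last
#'   artificial spacer.
#' @param total_length MOE primer length (default 50 nt).
#' @param arm_length optional explicit arm length.
#' @param overlap flank primer overlap passed to internal rv/fw design.
#' @param anchor_left,anchor_right names of the retained backbone spacers
#'   the arms sit on (defaults: first spacer and fifth spacer).
#' @return list with `moe_fw`, `moe_rv` (`mc_primer`), `left_unit`,
#'   `right_unit` (`flank_unit`), and `arm_length`.
#' @export
design_moe_primers <- function(backbone, first_new_spacer, last_new_spacer,
                               total_length = 50L, arm_length = NULL,
                               overlap = 12L,
                               anchor_left = NULL, anchor_right = NULL) {
  stopifnot(inherits(backbone, "minicr_backbone"))
  rep_seq <- backbone$repeat_seq
  r <- nchar(rep_seq)
  total_length <- as.integer(total_length)
  if (is.null(arm_length)) arm_length <- total_length - r
  arm_length <- as.integer(arm_length)
  if (arm_length < MIN_PRIMER_LENGTH) {
    mc_error(sprintf(
      "MOE total length %d nt leaves a %d-nt spacer arm; at least %d nt is needed",
      total_length, arm_length, MIN_PRIMER_LENGTH), "minicr_primer_error")
  }
  rep_portion <- total_length - arm_length
  if (rep_portion < 1L || rep_portion > r) {
    mc_error(sprintf("repeat portion %d nt infeasible for a %d-nt repeat",
                     rep_portion, r), "minicr_primer_error")
  }
  nm <- names(backbone$spacers)
  if (is.null(anchor_left)) anchor_left <- nm[1]
  if (is.null(anchor_right)) anchor_right <- nm[min(5L, length(nm))]
  d1 <- backbone$spacers[[anchor_left]]
  d5 <- backbone$spacers[[anchor_right]]
  if (nchar(d1) < arm_length || nchar(d5) < arm_length) {
    mc_error(sprintf("anchor spacers shorter than the %d-nt arm", arm_length),
             "minicr_primer_error")
  }
  arm_fw <- substr(d1, nchar(d1) - arm_length + 1L, nchar(d1))
  arm_rv <- substr(d5, 1L, arm_length)
  moe_fw <- new_primer("MOE_fw",
                       paste0(arm_fw, substr(rep_seq, 1L, rep_portion)),
                       "moe_fw")
  moe_rv <- new_primer("MOE_rv",
                       revcomp_chr(paste0(substr(rep_seq, r - rep_portion + 1L, r),
                                          arm_rv), "DNA"),
                       "moe_rv")
  # terminal units: MOE primer on the anchor side, centred flank primer on
  # the new-spacer side
  b <- (r + overlap) %/% 2L
  left_rv <- new_primer(sprintf("flank_%s_S1_rv", anchor_left),
                        revcomp_chr(paste0(substr(rep_seq, r - b + 1L, r),
                                           toupper(first_new_spacer)), "DNA"),
                        "flank_rv")
  left_unit <- new_flank_unit(arm_fw, toupper(first_new_spacer),
                              moe_fw, left_rv,
                              paste0(arm_fw, rep_seq, toupper(first_new_spacer)),
                              left_label = paste0(anchor_left, "_arm"),
                              right_label = "S_first")
  right_fw <- new_primer(sprintf("flank_Sn_%s_fw", anchor_right),
                         paste0(toupper(last_new_spacer),
                                substr(rep_seq, 1L, b)),
                         "flank_fw")
  right_unit <- new_flank_unit(toupper(last_new_spacer), arm_rv,
                               right_fw, moe_rv,
                               paste0(toupper(last_new_spacer), rep_seq, arm_rv),
                               left_label = "S_last",
                               right_label = paste0(anchor_right, "_arm"))
  list(moe_fw = moe_fw, moe_rv = moe_rv,
       left_unit = left_unit, right_unit = right_unit,
       arm_length = arm_length)
}

#' Derive the M amplification primers from the MOE primers
#'
#' The M primers bind the spacer-specific arm of each MOE primer, so the OE
#' fragment amplifies only when every flank fused correctly end to end.
#'
#' @param moe_fw,moe_rv MOE primers from [design_moe_primers()].
#' @param arm_length the MOE arm length.
#' @return list with `m_fw`, `m_rv` (each a prefix of its MOE primer).
#' @export
design_m_primers <- function(moe_fw, moe_rv, arm_length) {
  list(m_fw = new_primer("M_fw", substr(moe_fw$seq, 1L, arm_length), "m_fw"),
       m_rv = new_primer("M_rv", substr(moe_rv$seq, 1L, arm_length), "m_rv"))
}

#' Design the complete OE-PCR primer set for a construct
#'
#' Convenience wrapper producing, for a backbone and an ordered list of new
#' spacers, the terminal units (anchored on the retained backbone spacers),
#' the internal flank units, and the MOE/M primers.
#'
#' @param backbone a [minicr_backbone()].
#' @param new_spacers ordered DNA spacers to insert.
#' @param overlap flank primer overlap (nt).
#' @param moe_total MOE primer total length (nt).
#' @return list with `units` (ordered flank units), `moe`, `m`,
#'   `arm_length`.
#' @export
design_oe_set <- function(backbone, new_spacers, overlap = 12L,
                          moe_total = 50L) {
  new_spacers <- vapply(new_spacers, toupper, "")
  n <- length(new_spacers)
  if (n == 0L) mc_error("no new spacers", "minicr_input_error")
  moe <- design_moe_primers(backbone, new_spacers[[1]], new_spacers[[n]],
                            total_length = moe_total, overlap = overlap)
  units <- list(moe$left_unit)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      units[[length(units) + 1L]] <- design_flank_unit(
        new_spacers[[i]], backbone$repeat_seq, new_spacers[[i + 1L]],
        overlap = overlap, names = c(paste0("S", i), paste0("S", i + 1L)))
    }
  }
  units[[length(units) + 1L]] <- moe$right_unit
  m <- design_m_primers(moe$moe_fw, moe$moe_rv, moe$arm_length)
  list(units = units, moe = moe[c("moe_fw", "moe_rv")], m = m,
       arm_length = moe$arm_length)
}

#' Simulate fusion of flank units into an OE fragment
#'
#' Products are joined wherever one unit's terminal (right) spacer equals
#' another unit's initial (left) spacer, over the full spacer sequence. The
#' fragment is accepted only if it is amplifiable by the M primers — it must
#' begin with the `m_fw` arm and end with the arm complementary to `m_rv` —
#' mirroring the selective amplification that only correctly fused flanks
#' survive. A spacer usable in more than one join (e.g. duplicated inner
#' spacers) raises an ambiguity error; units that cannot be chained raise a
#' no-amplicon error.
#'
#' @param flank_units list of `flank_unit`s (any order).
#' @param m_primers list with `m_fw`, `m_rv` from [design_m_primers()].
#' @return object of class `oe_fragment`: `seq`, `unit_trace`, `arm_fw`,
#'   `arm_rv` (both on the top strand).
#' @export
simulate_oe_fusion <- function(flank_units, m_primers) {
  if (length(flank_units) == 0L) {
    mc_error("at least one flank unit is required", "minicr_input_error")
  }
  arm_fw <- m_primers$m_fw$seq
  arm_rv <- revcomp_chr(m_primers$m_rv$seq, "DNA")
  lefts <- vapply(flank_units, `[[`, "", "left_spacer")
  rights <- vapply(flank_units, `[[`, "", "right_spacer")
  if (anyDuplicated(lefts) || anyDuplicated(rights) ||
      any(lefts == rights)) {
    mc_error(
      "ambiguous fusion: a spacer is usable in more than one join (duplicate inner spacers need the dosage route)",
      "minicr_ambiguous_fusion_error")
  }
  start_idx <- which(lefts == arm_fw)
  if (length(start_idx) == 0L) {
    mc_error("no flank carries the forward M arm: no amplicon",
             "minicr_no_amplicon_error")
  }
  idx <- start_idx[1]
  frag <- flank_units[[idx]]$product
  trace <- sprintf("%s|%s", flank_units[[idx]]$left_label,
                   flank_units[[idx]]$right_label)
  used <- idx
  current_right <- rights[idx]
  while (current_right != arm_rv) {
    nxt <- which(lefts == current_right)
    nxt <- setdiff(nxt, used)
    if (length(nxt) == 0L) {
      mc_error(sprintf(
        "fusion dead end after spacer '%s': disconnected flank set, no amplicon",
        flank_units[[used[length(used)]]]$right_label),
        "minicr_no_amplicon_error")
    }
    idx <- nxt[1]
    frag <- paste0(frag, substr(flank_units[[idx]]$product,
                                nchar(current_right) + 1L,
                                nchar(flank_units[[idx]]$product)))
    trace <- c(trace, sprintf("%s|%s", flank_units[[idx]]$left_label,
                              flank_units[[idx]]$right_label))
    used <- c(used, idx)
    current_right <- rights[idx]
  }
  if (length(used) < length(flank_units)) {
    mc_error("disconnected flank set: unfused flanks remain, no unique amplicon",
             "minicr_no_amplicon_error")
  }
  if (!startsWith(frag, arm_fw) || !endsWith(frag, arm_rv)) {
    mc_error("fused fragment is not flanked by the M primer arms: no amplicon",
             "minicr_no_amplicon_error")
  }
  structure(list(seq = frag, unit_trace = trace,
                 arm_fw = arm_fw, arm_rv = arm_rv),
            class = "oe_fragment")
}

#' @export
print.oe_fragment <- function(x, ...) {
  cat(sprintf("<oe_fragment> %d nt, %d unit(s)\n  %s\n", nchar(x$seq),
              length(x$unit_trace), paste(x$unit_trace, collapse = " + ")))
  invisible(x)
}

count_circular <- function(seq, pattern) {
  n <- nchar(seq)
  doubled <- paste0(seq, substr(seq, 1L, min(nchar(pattern) - 1L, n)))
  hits <- find_all(doubled, pattern)
  hits[hits <= n]
}

rotate_circular <- function(seq, k) {
  # rotate so that position k becomes position 1
  if (k == 1L) return(seq)
  paste0(substr(seq, k, nchar(seq)), substr(seq, 1L, k - 1L))
}

#' Simulate megaprimer insertion into a circular template
#'
#' The OE fragment acts as a long primer pair on the circular template
#' (whole-plasmid amplification): its two terminal arms anneal to their
#' single occurrences on the template and the span between them is replaced
#' by the fragment interior. Topology stays circular.
#'
#' @param fragment an `oe_fragment`.
#' @param template circular [nuc_seq()] (DNA).
#' @return circular [nuc_seq()] of the product, rotated to start at the
#'   forward arm.
#' @export
simulate_megaprimer_insertion <- function(fragment, template) {
  stopifnot(inherits(fragment, "oe_fragment"), inherits(template, "nuc_seq"))
  if (template$topology != "circular") {
    mc_error("template must be circular", "minicr_input_error")
  }
  seq <- template$seq
  hits_fw <- count_circular(seq, fragment$arm_fw)
  if (length(hits_fw) != 1L) {
    mc_error(sprintf(
      "forward arm occurs %d time(s) on template '%s' (exactly 1 required)",
      length(hits_fw), template$id), "minicr_arm_error")
  }
  rot <- rotate_circular(seq, hits_fw)
  hits_rv <- count_circular(rot, fragment$arm_rv)
  if (length(hits_rv) != 1L) {
    mc_error(sprintf(
      "reverse arm occurs %d time(s) on template '%s' (exactly 1 required)",
      length(hits_rv), template$id), "minicr_arm_error")
  }
  a <- nchar(fragment$arm_fw)
  q <- hits_rv
  if (q <= a) {
    mc_error("template arms overlap or are incompatibly oriented",
             "minicr_arm_error")
  }
  b <- nchar(fragment$arm_rv)
  rest <- substr(rot, q + b, nchar(rot))
  nuc_seq(paste0(template$id, "_inserted"), paste0(fragment$seq, rest),
          alphabet = "DNA", topology = "circular")
}

#' Design the dosage route (repeated spacer by inverse PCR + overlap primers)
#'
#' For a construct carrying the spacer once: linearisation primers split the
#' spacer at its midpoint facing outward (inverse PCR); the overlap primers
#' are `second half of spacer + repeat + full spacer` (about 80 nt for a
#' 37-nt spacer and a 24-nt repeat) and their annealing regenerates the
#' junction, so each round adds one repeat-spacer unit. The simulated
#' product carries the spacer `copies` times in series, interspaced by
#' repeats, at the original locus position.
#'
#' @param construct a `minicr_construct` containing `spacer` exactly once.
#' @param spacer DNA spacer to multiply.
#' @param copies total copy number wanted (`1` returns the input construct).
#' @return list with `lin_fw`, `lin_rv`, `over_fw`, `over_rv`
#'   (`mc_primer`s) and `product` (a `minicr_construct`).
#' @export
design_dosage_route <- function(construct, spacer, copies) {
  stopifnot(inherits(construct, "minicr_construct"))
  spacer <- toupper(spacer)
  copies <- as.integer(copies)
  if (copies < 1L) mc_error("copies must be >= 1", "minicr_input_error")
  hit <- which(construct$spacers == spacer)
  if (length(hit) != 1L) {
    mc_error(sprintf(
      "spacer must occur exactly once in the construct (found %d times)",
      length(hit)), "minicr_spacer_error")
  }
  L <- nchar(spacer)
  mid <- L %/% 2L
  half1 <- substr(spacer, 1L, mid)
  half2 <- substr(spacer, mid + 1L, L)
  lin_fw <- new_primer("MA_lin_fw", half2, "lin_fw")
  lin_rv <- new_primer("MA_lin_rv", revcomp_chr(half1, "DNA"), "lin_rv")
  over_fw <- new_primer("MA_over_fw",
                        paste0(half2, construct$repeat_seq, spacer), "over")
  over_rv <- new_primer("MA_over_rv",
                        revcomp_chr(paste0(spacer, construct$repeat_seq, half1),
                                    "DNA"), "over")
  if (copies == 1L) {
    return(list(lin_fw = lin_fw, lin_rv = lin_rv,
                over_fw = over_fw, over_rv = over_rv,
                product = construct))
  }
  spacers <- construct$spacers
  prov <- construct$provenance
  i <- hit
  new_names <- paste0(names(spacers)[i], "_c", seq_len(copies))
  spacers <- append(spacers[-i], stats::setNames(rep(spacer, copies), new_names),
                    after = i - 1L)
  prov <- append(prov[-i], stats::setNames(rep(prov[[i]], copies), new_names),
                 after = i - 1L)
  product <- structure(list(
    name = paste0(construct$name, "_x", copies),
    leader_seq = construct$leader_seq,
    repeat_seq = construct$repeat_seq,
    spacers = spacers,
    provenance = prov,
    full_seq = build_full_seq(construct$leader_seq, construct$repeat_seq,
                              spacers)),
    class = "minicr_construct")
  list(lin_fw = lin_fw, lin_rv = lin_rv,
       over_fw = over_fw, over_rv = over_rv,
       product = product)
}

#' Write a primer set as an order sheet (TSV) and/or FASTA
#'
#' @param primers list of `mc_primer`s (nested lists are flattened).
#' @param tsv_path order-sheet destination (name, sequence, role, length);
#'   `NULL` to skip.
#' @param fasta_path FASTA destination; `NULL` to skip.
#' @param protocol optional named list of protocol metadata (e.g. template
#'   ratios) written as `#` header lines of the TSV.
#' @return data.frame order sheet, invisibly.
#' @export
write_primer_sheet <- function(primers, tsv_path = NULL, fasta_path = NULL,
                               protocol = NULL) {
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "mc_primer")) flat[[length(flat) + 1L]] <<- x
    else if (is.list(x)) lapply(x, collect)
  }
  collect(primers)
  sheet <- data.frame(
    name = vapply(flat, `[[`, "", "name"),
    sequence = vapply(flat, `[[`, "", "seq"),
    role = vapply(flat, `[[`, "", "role"),
    length = vapply(flat, function(p) nchar(p$seq), 0L),
    stringsAsFactors = FALSE)
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    if (!is.null(protocol)) {
      for (nm in names(protocol)) {
        writeLines(sprintf("# %s: %s", nm, protocol[[nm]]), con)
      }
    }
    utils::write.table(sheet, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  if (!is.null(fasta_path)) {
    write_fasta(stats::setNames(sheet$sequence, sheet$name), fasta_path)
  }
  invisible(sheet)
}
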