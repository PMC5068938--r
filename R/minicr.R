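# miniCRISPR locus assembly: leader + repeat-spacer array, transcription of
# the array, and in-silico maturation into crRNAs.

#' Define a miniCRISPR backbone
#'
#' The natural template: a leader (carrying the promoter) followed by an
#' array of named spacers interspaced by identical repeats. The default
#' naming D1..D6 mirrors a locus trimmed to its leader-proximal spacers.
#'
#' @param leader_seq DNA leader.
#' @param repeat_seq DNA repeat (at least 8 nt, so a handle can be derived).
#' @param spacers named character vector/list of DNA spacers, in array
#'   order; at least 2.
#' @return object of class `minicr_backbone`.
#' @export
minicr_backbone <- function(leader_seq, repeat_seq, spacers) {
  leader_seq <- toupper(leader_seq); repeat_seq <- toupper(repeat_seq)
  check_alphabet(leader_seq, "DNA", "leader")
  check_alphabet(repeat_seq, "DNA", "repeat")
  if (nchar(repeat_seq) < 8L) {
    mc_error("repeat must be at least 8 nt (handle source)",
             "minicr_repeat_error")
  }
  spacers <- vapply(spacers, toupper, "")
  if (length(spacers) < 2L) {
    mc_error("backbone needs at least 2 spacers", "minicr_input_error")
  }
  if (is.null(names(spacers)) || any(!nzchar(names(spacers)))) {
    names(spacers) <- paste0("D", seq_along(spacers))
  }
  for (nm in names(spacers)) check_alphabet(spacers[[nm]], "DNA", nm)
  structure(list(leader_seq = leader_seq, repeat_seq = repeat_seq,
                 spacers = spacers),
            class = "minicr_backbone")
}

check_spacer_insertable <- function(spacer, name, repeat_seq) {
  if (!nzchar(spacer)) {
    mc_error(sprintf("spacer '%s' is empty", name), "minicr_spacer_error")
  }
  if (grepl(repeat_seq, spacer, fixed = TRUE)) {
    mc_error(sprintf(
      "spacer '%s' contains the repeat sequence; the array would be misprocessed",
      name), "minicr_spacer_error")
  }
  invisible(TRUE)
}

build_full_seq <- function(leader, repeat_seq, spacers) {
  paste0(leader, repeat_seq,
         paste0(vapply(spacers, paste0, "", repeat_seq), collapse = ""))
}

#' Assemble a miniCRISPR construct
#'
#' Under the default mode the backbone's second through fourth spacers are
#' replaced by the new (artificial) spacers, giving the array
#' D1, new..., D5, D6; the leader and the remaining backbone spacers are
#' retained. The array carries `n` spacers and `n + 1` repeats (a terminal
#' repeat closes the array). Identical new spacers are accepted (dosage
#' designs).
#'
#' @param backbone a [minicr_backbone()].
#' @param new_spacers character vector of DNA spacers (named or not).
#' @param mode `"replace_D2_D4"` (default) or `"insert_after"`.
#' @param insert_after backbone spacer name after which to insert when
#'   `mode = "insert_after"`.
#' @param name construct name.
#' @return object of class `minicr_construct` with `spacers` (named DNA
#'   vector in array order), `provenance` (`"backbone"`/`"artificial"` per
#'   spacer) and `full_seq`.
#' @export
assemble_minicr <- function(backbone, new_spacers,
                            mode = c("replace_D2_D4", "insert_after"),
                            insert_after = NULL, name = "miniCR") {
  stopifnot(inherits(backbone, "minicr_backbone"))
  mode <- match.arg(mode)
  if (length(new_spacers) == 0L) {
    mc_error("new_spacers must be non-empty", "minicr_input_error")
  }
  new_spacers <- vapply(new_spacers, toupper, "")
  if (is.null(names(new_spacers)) || any(!nzchar(names(new_spacers)))) {
    names(new_spacers) <- paste0("S", seq_along(new_spacers))
  }
  for (i in seq_along(new_spacers)) {
    check_alphabet(new_spacers[[i]], "DNA", names(new_spacers)[i])
    check_spacer_insertable(new_spacers[[i]], names(new_spacers)[i],
                            backbone$repeat_seq)
  }
  bs <- backbone$spacers
  if (mode == "replace_D2_D4") {
    if (length(bs) < 5L) {
      mc_error("replace_D2_D4 mode needs a backbone with at least 5 spacers",
               "minicr_input_error")
    }
    spacers <- c(bs[1L], new_spacers, bs[5L:length(bs)])
    prov <- c("backbone", rep("artificial", length(new_spacers)),
              rep("backbone", length(bs) - 4L))
  } else {
    if (is.null(insert_after) || !insert_after %in% names(bs)) {
      mc_error("insert_after must name a backbone spacer",
               "minicr_input_error")
    }
    idx <- match(insert_after, names(bs))
    spacers <- append(bs, new_spacers, after = idx)
    prov <- rep("backbone", length(bs))
    prov <- append(prov, rep("artificial", length(new_spacers)), after = idx)
  }
  names(prov) <- names(spacers)
  structure(list(name = name,
                 leader_seq = backbone$leader_seq,
                 repeat_seq = backbone$repeat_seq,
                 spacers = spacers,
                 provenance = prov,
                 full_seq = build_full_seq(backbone$leader_seq,
                                           backbone$repeat_seq, spacers)),
            class = "minicr_construct")
}

#' @export
print.minicr_construct <- function(x, ...) {
  cat(sprintf("<minicr_construct> %s: leader(%d nt) + %d spacers / %d repeats (%d nt total)\n",
              x$name, nchar(x$leader_seq), length(x$spacers),
              length(x$spacers) + 1L, nchar(x$full_seq)))
  cat("  array:", paste(sprintf("%s[%s]", names(x$spacers),
                                substr(x$provenance, 1, 1)),
                        collapse = " - "), "\n")
  invisible(x)
}

#' Transcribe the array portion of a construct
#'
#' Transcription starts at the first repeat (the leader is treated as
#' promoter only) and runs through the terminal repeat.
#'
#' @param construct a `minicr_construct`.
#' @return RNA [nuc_seq()] of the precursor transcript.
#' @export
locus_transcript <- function(construct) {
  stopifnot(inherits(construct, "minicr_construct"))
  array_dna <- substr(construct$full_seq, nchar(construct$leader_seq) + 1L,
                      nchar(construct$full_seq))
  nuc_seq(paste0(construct$name, "_pre_crRNA"), transcribe_chr(array_dna),
          alphabet = "RNA")
}

#' Mature crRNAs of a construct
#'
#' One crRNA per spacer, in array order: an 8-nt handle (transcribed tail of
#' the upstream repeat) followed by the transcribed spacer. 3' trimming is
#' not modelled (the full spacer is retained).
#'
#' @param construct a `minicr_construct`.
#' @return list of `crrna` objects (`handle_rna`, `spacer_rna`,
#'   `spacer_name`, `array_index`).
#' @export
mature_crrnas <- function(construct) {
  stopifnot(inherits(construct, "minicr_construct"))
  if (nchar(construct$repeat_seq) < 8L) {
    mc_error("repeat shorter than 8 nt: no handle can be produced",
             "minicr_repeat_error")
  }
  handle <- handle_from_repeat(construct$repeat_seq)
  lapply(seq_along(construct$spacers), function(i) {
    structure(list(handle_rna = handle$handle_rna,
                   spacer_rna = transcribe_chr(construct$spacers[[i]]),
                   spacer_name = names(construct$spacers)[i],
                   array_index = i),
              class = "crrna")
  })
}

#' @export
print.crrna <- function(x, ...) {
  cat(sprintf("<crrna> #%d %s: 5'-%s|%s-3'\n", x$array_index, x$spacer_name,
              x$handle_rna, x$spacer_rna))
  invisible(x)
}

#' Validate a construct
#'
#' Structural report: repeat count, spacer length range (default 37-40 nt,
#' covering both targeting and nonsense control spacers), repeat substrings
#' inside spacers, and duplicate spacers (a warning — duplicated inner
#' spacers break the standard overlap-extension route and require the
#' dosage construction instead).
#'
#' @param construct a `minicr_construct`.
#' @param expected_spacer_lengths length-2 vector, allowed spacer length
#'   range.
#' @return data.frame report (`check`, `level`, `spacer`, `message`); zero
#'   rows when clean.
#' @export
validate_construct <- function(construct,
                               expected_spacer_lengths = c(37L, 40L)) {
  stopifnot(inherits(construct, "minicr_construct"))
  rows <- list()
  add <- function(check, level, spacer, message) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, level = level, spacer = spacer, message = message,
      stringsAsFactors = FALSE)
  }
  rebuilt <- build_full_seq(construct$leader_seq, construct$repeat_seq,
                            construct$spacers)
  if (!identical(rebuilt, construct$full_seq)) {
    add("full_seq", "violation", NA_character_,
        "stored full_seq does not match reconstruction from the array model")
  }
  lens <- nchar(construct$spacers)
  lo <- expected_spacer_lengths[1]; hi <- expected_spacer_lengths[2]
  for (i in which(lens < lo | lens > hi)) {
    add("spacer_length", "violation", names(construct$spacers)[i],
        sprintf("spacer length %d nt outside %d-%d nt", lens[i], lo, hi))
  }
  for (i in which(vapply(construct$spacers, grepl, TRUE,
                         pattern = construct$repeat_seq, fixed = TRUE))) {
    add("repeat_in_spacer", "violation", names(construct$spacers)[i],
        "spacer contains the repeat sequence")
  }
  dup <- construct$spacers[duplicated(construct$spacers)]
  for (s in unique(names(dup))) {
    add("duplicate_spacer", "warning", s,
        "duplicated spacer: standard OE-PCR fusion is ambiguous; use the dosage (inverse PCR + overlap primer) route")
  }
  if (length(rows) == 0L) {
    return(data.frame(check = character(), level = character(),
                      spacer = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write a construct as GenBank-style flat file
#'
#' Minimal writer: LOCUS/FEATURES/ORIGIN with leader, repeat and spacer
#' features (spacer features carry a `/provenance` qualifier).
#'
#' @param construct a `minicr_construct`.
#' @param path output file.
#' @export
write_construct_genbank <- function(construct, path) {
  feats <- construct_features(construct)
  write_genbank_flat(construct$name, construct$full_seq, feats, path)
}

construct_features <- function(construct) {
  rl <- nchar(construct$repeat_seq)
  pos <- nchar(construct$leader_seq)
  rows <- list(data.frame(type = "misc_feature", start = 1L, end = pos,
                          label = "leader", provenance = NA_character_,
                          stringsAsFactors = FALSE))
  add_repeat <- function(p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = "repeat_region", start = p + 1L, end = p + rl,
      label = "repeat", provenance = NA_character_, stringsAsFactors = FALSE)
  }
  add_repeat(pos); pos <- pos + rl
  for (i in seq_along(construct$spacers)) {
    sl <- nchar(construct$spacers[[i]])
    rows[[length(rows) + 1L]] <- data.frame(
      type = "misc_feature", start = pos + 1L, end = pos + sl,
      label = names(construct$spacers)[i],
      provenance = construct$provenance[[i]], stringsAsFactors = FALSE)
    pos <- pos + sl
    add_repeat(pos); pos <- pos + rl
  }
  do.call(rbind, rows)
}

write_genbank_flat <- function(name, seq, features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     linear   %s",
                     name, nchar(seq), format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s.", name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", nchar(seq)), con)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    writeLines(sprintf("     %-15s %d..%d", f$type, f$start, f$end), con)
    writeLines(sprintf("                     /label=\"%s\"", f$label), con)
    if (!is.na(f$provenance)) {
      writeLines(sprintf("                     /provenance=\"%s\"",
                         f$provenance), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(seq)
  for (off in seq(1L, nchar(s), by = 60L)) {
    chunk <- substr(s, off, min(off + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read CDS features from a GenBank flat file
#'
#' Minimal reader for GenBank records: parses the ORIGIN sequence and CDS
#' features (`start..end` or `complement(start..end)`, with `/locus_tag`),
#' sufficient for CDS extraction. Join locations are flattened into their
#' segments with a warning.
#'
#' @param path GenBank file.
#' @return list with `genome` ([nuc_seq()]) and `annotation` (data.frame
#'   for [extract_cds()]).
#' @export
read_genbank_cds <- function(path) {
  if (!file.exists(path)) {
    mc_error(sprintf("file not found: %s", path), "minicr_io_error")
  }
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  name <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])),
                                      "\\s+")[[1]][1] else "genbank"
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) {
    mc_error("no ORIGIN section", "minicr_io_error")
  }
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feat_idx <- grep("^\\s{5}CDS\\s+", lines)
  rows <- list()
  for (i in feat_idx) {
    loc <- trimws(sub("^\\s{5}CDS\\s+", "", lines[i]))
    j <- i + 1L
    while (j <= length(lines) && grepl("^\\s{21}[^/]", lines[j])) {
      loc <- paste0(loc, trimws(lines[j])); j <- j + 1L
    }
    strand <- if (grepl("complement", loc)) "-" else "+"
    if (grepl("join", loc)) {
      mc_warn(sprintf("join location flattened: %s", loc),
              "minicr_multisegment_warning")
    }
    segs <- regmatches(loc, gregexpr("[0-9]+\\.\\.[0-9]+", loc))[[1]]
    if (length(segs) == 0L) {
      mc_error(sprintf("unparseable CDS location: %s", loc),
               "minicr_io_error")
    }
    tag <- NA_character_
    while (j <= length(lines) && grepl("^\\s{21}/", lines[j])) {
      m <- regmatches(lines[j], regexec("/locus_tag=\"([^\"]+)\"", lines[j]))[[1]]
      if (length(m) == 2L) tag <- m[2]
      j <- j + 1L
    }
    if (is.na(tag)) tag <- sprintf("CDS_%d", i)
    for (s in segs) {
      se <- as.integer(strsplit(s, "..", fixed = TRUE)[[1]])
      rows[[length(rows) + 1L]] <- data.frame(
        locus_tag = tag, start = se[1], end = se[2], strand = strand,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    mc_error(sprintf("no CDS features in %s", path), "minicr_empty_error")
  }
  list(genome = nuc_seq(name, seq, alphabet = "DNA"),
       annotation = do.call(rbind, rows))
}
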