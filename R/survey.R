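# Genome-wide availability of the minimal PAS motif: per-CDS occurrence
# counts and genome-level fractions.

#' Count minimal PAS-motif occurrences in one CDS
#'
#' Counts every mRNA position whose trinucleotide belongs to the minimal
#' motif set of the handle (see [minimal_motif_patterns()]). Occurrences may
#' overlap: every position is tested independently. With
#' `require_upstream_room = TRUE` (default) only positions with at least
#' `protospacer_length + 2` nt upstream are counted, so a full protospacer
#' fits 5' of the motif (the motif sits at PAS positions +3..+5, two
#' nucleotides downstream of the protospacer end).
#'
#' @param cds a `cds_record` (from [extract_cds()]) or an RNA string.
#' @param handle a [handle_spec()].
#' @param config a [pas_config()].
#' @param require_upstream_room only count usable sites (default `TRUE`).
#' @param protospacer_length protospacer length used for the room check.
#' @return integer occurrence count.
#' @export
count_motif_occurrences <- function(cds, handle, config = pas_config(),
                                    require_upstream_room = TRUE,
                                    protospacer_length = 37L) {
  seq <- if (inherits(cds, "cds_record")) cds$mrna_seq else toupper(seq_chr(cds))
  check_alphabet(seq, "RNA", "cds")
  patterns <- minimal_motif_patterns(handle, config)
  n <- nchar(seq)
  if (n < 3L || length(patterns) == 0L) return(0L)
  pos <- seq_len(n - 2L)
  if (require_upstream_room) {
    pos <- pos[pos >= protospacer_length + 3L]
    if (length(pos) == 0L) return(0L)
  }
  sum(substring(seq, pos, pos + 2L) %in% patterns)
}

#' Survey a CDS set for minimal PAS-motif availability
#'
#' Applies [count_motif_occurrences()] to every CDS and reports, for each
#' threshold `k`, the percentage of CDS carrying at least `k` occurrences.
#' Raw fractions are retained; rounding is left to presentation.
#'
#' @param cds_list list of `cds_record`s (or named RNA strings).
#' @param handle a [handle_spec()].
#' @param config a [pas_config()].
#' @param thresholds occurrence thresholds (default `c(1, 5)`).
#' @param require_upstream_room,protospacer_length passed through to
#'   [count_motif_occurrences()].
#' @param annotation_source free-text provenance of the CDS annotation,
#'   echoed into the result.
#' @return object of class `survey_result`: `per_cds` data.frame
#'   (`locus_tag`, `cds_length`, `motif_count`), `fraction_at_least`
#'   (named percentages), and `config_echo`.
#' @export
survey_cds <- function(cds_list, handle, config = pas_config(),
                       thresholds = c(1L, 5L),
                       require_upstream_room = TRUE,
                       protospacer_length = 37L,
                       annotation_source = "unspecified") {
  if (length(cds_list) == 0L) {
    mc_error("empty CDS list", "minicr_empty_error")
  }
  tags <- vapply(seq_along(cds_list), function(i) {
    x <- cds_list[[i]]
    if (inherits(x, "cds_record")) x$locus_tag
    else if (!is.null(names(cds_list))) names(cds_list)[i]
    else sprintf("cds_%03d", i)
  }, "")
  lens <- vapply(cds_list, function(x)
    nchar(if (inherits(x, "cds_record")) x$mrna_seq else seq_chr(x)), 0L)
  counts <- vapply(cds_list, count_motif_occurrences, 0L,
                   handle = handle, config = config,
                   require_upstream_room = require_upstream_room,
                   protospacer_length = protospacer_length)
  thresholds <- sort(unique(as.integer(thresholds)))
  frac <- vapply(thresholds, function(k) 100 * mean(counts >= k), 0)
  names(frac) <- as.character(thresholds)
  structure(list(
    per_cds = data.frame(locus_tag = tags, cds_length = lens,
                         motif_count = counts, stringsAsFactors = FALSE),
    fraction_at_least = frac,
    thresholds = thresholds,
    config_echo = list(
      handle_rna = handle$handle_rna,
      wobble_counts_as_paired = config$wobble_counts_as_paired,
      minimal_positions = config$minimal_positions,
      require_upstream_room = require_upstream_room,
      protospacer_length = protospacer_length,
      annotation_source = annotation_source,
      n_cds = length(cds_list))
  ), class = "survey_result")
}

#' @export
print.survey_result <- function(x, ...) {
  cat(sprintf("<survey_result> %d CDS, handle 5'-%s-3', wobble=%s, upstream_room=%s\n",
              x$config_echo$n_cds, x$config_echo$handle_rna,
              x$config_echo$wobble_counts_as_paired,
              x$config_echo$require_upstream_room))
  for (k in names(x$fraction_at_least)) {
    cat(sprintf("  >= %s occurrence(s): %.1f%% of CDS\n",
                k, x$fraction_at_least[[k]]))
  }
  invisible(x)
}

#' Write a survey result (per-CDS TSV + JSON summary)
#'
#' @param result a `survey_result`.
#' @param tsv_path per-CDS table destination (or `NULL` to skip).
#' @param json_path summary destination (or `NULL` to skip).
#' @export
write_survey <- function(result, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(result$per_cds, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(fraction_at_least = as.list(result$fraction_at_least),
           config = result$config_echo),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
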