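# qPCR and substrate-consumption quantification helpers: standard curves,
# delta-delta-Ct relative expression, copies per chromosome, and relative
# consumption.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 copy number. The amplification
#' efficiency follows from the slope as `10^(-1/slope) - 1` (a perfect
#' doubling per cycle gives slope -1/log10(2) = -3.3219 and efficiency 1).
#'
#' @param points data.frame with columns `log10_copies` and `ct` (at least
#'   3 points; the dilution series should span at least 2 log10 units).
#' @return object of class `standard_curve` with `slope`, `intercept`,
#'   `efficiency`, `r_squared` and the fitted `lm`.
#' @export
fit_standard_curve <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("log10_copies", "ct") %in% names(points))) {
    mc_error("points must have columns log10_copies and ct",
             "minicr_input_error")
  }
  if (nrow(points) < 3L) {
    mc_error("at least 3 standard points are required",
             "minicr_input_error")
  }
  span <- diff(range(points$log10_copies))
  if (span == 0) {
    mc_error("degenerate standard series: all points at one concentration",
             "minicr_input_error")
  }
  if (span < 2) {
    mc_warn(sprintf(
      "standard series spans only %.2f log10 units (2 or more recommended)",
      span), "minicr_span_warning")
  }
  fit <- stats::lm(ct ~ log10_copies, data = points)
  slope <- unname(stats::coef(fit)[["log10_copies"]])
  if (slope >= 0) {
    mc_error("standard-curve slope is non-negative; Ct must fall with copies",
             "minicr_input_error")
  }
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 fit = fit,
                 points = points),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.4f, intercept %.3f, efficiency %.1f%%, R2 %.4f\n",
    x$slope, x$intercept, 100 * x$efficiency, x$r_squared))
  invisible(x)
}

back_calc_copies <- function(ct, curve) {
  10^((ct - curve$intercept) / curve$slope)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `ddct = (ct_target_sample - ct_ref_sample) - (ct_target_control -
#' ct_ref_control)`; the result is `100 * (1 + efficiency)^(-ddct)`, i.e.
#' percent of the control. With the default efficiency 1 the base is 2
#' (classic 2^-ddct); supply the fitted efficiency for an
#' efficiency-corrected base.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the sample.
#' @param ct_target_control,ct_ref_control same for the control culture.
#' @param efficiency amplification efficiency in (0, 1].
#' @return percent of control (numeric).
#' @export
relative_expression_ddct <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_control, ct_ref_control,
                                     efficiency = 1) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_control,
           ct_ref_control)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    mc_error("all Ct values must be positive", "minicr_input_error")
  }
  if (!is.finite(efficiency) || efficiency <= 0 || efficiency > 1) {
    mc_error("efficiency must lie in (0, 1]", "minicr_input_error")
  }
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  100 * (1 + efficiency)^(-ddct)
}

#' Target copies per chromosome
#'
#' Back-calculates absolute copies of a (e.g. viral) target and of the host
#' chromosome from their standard curves on the same sample and returns the
#' ratio.
#'
#' @param viral_ct,chromosomal_ct measured Ct values.
#' @param curve_viral,curve_chrom fitted [fit_standard_curve()] objects.
#' @return copies-per-chromosome ratio.
#' @export
copies_per_chromosome <- function(viral_ct, chromosomal_ct,
                                  curve_viral, curve_chrom) {
  stopifnot(inherits(curve_viral, "standard_curve"),
            inherits(curve_chrom, "standard_curve"))
  back_calc_copies(viral_ct, curve_viral) /
    back_calc_copies(chromosomal_ct, curve_chrom)
}

#' Relative substrate consumption per chromosome
#'
#' Consumption between two timepoints, blank-corrected and normalised per
#' chromosome, expressed relative to a control culture:
#' `consumption = ((abs_t0 - blank) - (abs_t2 - blank)) / chromosomes`
#' (the blank cancels in the difference but is accepted for completeness);
#' the result is `100 * sample / control`.
#'
#' @param sample_abs_t0,sample_abs_t2 sample absorbances at the start and
#'   end of the interval.
#' @param blank_abs medium-only absorbance.
#' @param sample_chromosomes chromosome count (qPCR) of the sample.
#' @param control_triplet list/vector `(abs_t0, abs_t2, chromosomes)` for
#'   the control culture.
#' @return percent of control consumption.
#' @export
relative_consumption <- function(sample_abs_t0, sample_abs_t2, blank_abs,
                                 sample_chromosomes, control_triplet) {
  ct <- unlist(control_triplet, use.names = FALSE)
  if (length(ct) != 3L) {
    mc_error("control_triplet must supply (abs_t0, abs_t2, chromosomes)",
             "minicr_input_error")
  }
  consumption <- function(a0, a2, chrom) ((a0 - blank_abs) - (a2 - blank_abs)) / chrom
  ctl <- consumption(ct[1], ct[2], ct[3])
  if (!is.finite(ctl) || ctl <= 0) {
    mc_error("control consumption is zero or negative",
             "minicr_input_error")
  }
  100 * consumption(sample_abs_t0, sample_abs_t2, sample_chromosomes) / ctl
}

#' Read a Ct table (TSV)
#'
#' Expected columns: `sample_id`, `primer_pair`, `ct`, `replicate`.
#'
#' @param path TSV file (lines starting with `#` are skipped).
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) {
    mc_error(sprintf("file not found: %s", path), "minicr_io_error")
  }
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "primer_pair", "ct", "replicate")
  if (!all(need %in% names(df))) {
    mc_error(paste("Ct table must have columns",
                   paste(need, collapse = ", ")), "minicr_input_error")
  }
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) {
    mc_error("all Ct values must be positive", "minicr_input_error")
  }
  df
}

#' Delta-delta-Ct analysis of a replicated Ct table
#'
#' Replicate Cts are averaged (arithmetic mean) per sample and primer pair
#' before the delta-delta-Ct computation; the replicate SDs are propagated
#' (in Ct space, assuming independence) and reported on the percentage
#' scale.
#'
#' @param ct_table data.frame from [read_ct_table()].
#' @param target_pair,ref_pair primer pair labels of the target and
#'   reference gene.
#' @param control_id `sample_id` of the control culture.
#' @param efficiency amplification efficiency in (0, 1].
#' @return data.frame `sample_id`, `ddct`, `ddct_sd`, `percent_of_control`,
#'   `percent_sd`.
#' @export
ddct_table <- function(ct_table, target_pair, ref_pair, control_id,
                       efficiency = 1) {
  agg <- stats::aggregate(ct ~ sample_id + primer_pair, ct_table,
                          function(x) c(mean = mean(x),
                                        var = if (length(x) > 1L)
                                          stats::var(x) / length(x) else 0))
  agg <- cbind(agg[c("sample_id", "primer_pair")],
               as.data.frame(agg$ct))
  get <- function(sid, pair, what) {
    row <- agg[agg$sample_id == sid & agg$primer_pair == pair, ]
    if (nrow(row) != 1L) {
      mc_error(sprintf("no measurements for sample '%s', primer pair '%s'",
                       sid, pair), "minicr_input_error")
    }
    row[[what]]
  }
  samples <- setdiff(unique(ct_table$sample_id), control_id)
  dct_ctl <- get(control_id, target_pair, "mean") -
    get(control_id, ref_pair, "mean")
  var_ctl <- get(control_id, target_pair, "var") +
    get(control_id, ref_pair, "var")
  base <- 1 + efficiency
  out <- lapply(samples, function(sid) {
    ddct <- (get(sid, target_pair, "mean") - get(sid, ref_pair, "mean")) -
      dct_ctl
    sd <- sqrt(get(sid, target_pair, "var") + get(sid, ref_pair, "var") +
                 var_ctl)
    pct <- 100 * base^(-ddct)
    data.frame(sample_id = sid, ddct = ddct, ddct_sd = sd,
               percent_of_control = pct,
               percent_sd = pct * log(base) * sd,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
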