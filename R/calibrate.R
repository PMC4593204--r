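#' Fit the allelic signal-bias calibration for one marker
#'
#' Standard mixtures of the two alleles at known molar ratios reveal any
#' systematic signal excess of one allele (dye incorporation, conformer
#' separation efficiency).  The bias is estimated in log space as
#' `exp(mean(log(observed ratio) - log(known ratio)))`, i.e. a single
#' multiplicative factor per marker; `residual_sd` is the standard
#' deviation of the log-residuals and summarises how well a constant bias
#' explains the series.
#'
#' @param standards Tibble of calibration records with columns `locus_id`,
#'   `known_ratio`, `height_allele1`, `height_allele2` (the schema written
#'   by [emit_standard_series()]).  All rows must belong to one locus.
#' @return An object of class `ase_calibration` with fields `locus_id`,
#'   `bias`, `n_points`, `residual_sd`.
#' @examples
#' std <- tibble::tibble(locus_id = "rs1690916", known_ratio = c(1, 2),
#'                       height_allele1 = c(1500, 3000),
#'                       height_allele2 = c(1000, 1000))
#' fit_calibration(std)  # bias 1.5
#' @export
fit_calibration <- function(standards) {
  needed <- c("locus_id", "known_ratio", "height_allele1", "height_allele2")
  if (!all(needed %in% names(standards)) || nrow(standards) < 1) {
    abort("standards must have >= 1 row with locus_id, known_ratio and both heights")
  }
  if (length(unique(standards$locus_id)) != 1) {
    abort("fit_calibration() expects standards for a single locus; split by locus_id")
  }
  if (any(!is.finite(standards$known_ratio) | standards$known_ratio <= 0)) {
    abort("every known_ratio must be positive")
  }
  if (any(standards$height_allele1 <= 0 | standards$height_allele2 <= 0)) {
    abort("calibration standards are two-allele mixtures; zero peak heights are invalid")
  }
  resid <- log(standards$height_allele1 / standards$height_allele2) -
    log(standards$known_ratio)
  structure(list(
    locus_id = standards$locus_id[1],
    bias = exp(mean(resid)),
    n_points = nrow(standards),
    residual_sd = if (length(resid) > 1) sd(resid) else 0
  ), class = "ase_calibration")
}

#' Fit calibrations for every marker in a standards table
#'
#' @param standards Calibration records for one or more loci.
#' @return Named list of `ase_calibration` objects, one per `locus_id`.
#' @export
fit_calibrations <- function(standards) {
  split(standards, standards$locus_id) |> lapply(fit_calibration)
}

#' Construct a unit (or explicit) calibration without standards
#'
#' Used when a marker's signal response is taken as unbiased, or when an
#' externally determined bias is supplied.
#'
#' @param locus_id Marker locus id.
#' @param bias Positive bias factor.
#' @return An `ase_calibration`.
#' @export
calibration_override <- function(locus_id, bias = 1) {
  if (!is.finite(bias) || bias <= 0) abort("bias must be positive")
  structure(list(locus_id = locus_id, bias = bias, n_points = 0L,
                 residual_sd = NA_real_),
            class = "ase_calibration")
}

#' @export
print.ase_calibration <- function(x, ...) {
  cat(sprintf("Calibration for %s: bias %.4f (%d standards, log-residual sd %s)\n",
              x$locus_id, x$bias, x$n_points,
              ifelse(is.na(x$residual_sd), "NA", sprintf("%.4f", x$residual_sd))))
  invisible(x)
}

#' @export
tidy.ase_calibration <- function(x, ...) {
  tibble(locus_id = x$locus_id, term = "bias", estimate = x$bias)
}

#' @export
glance.ase_calibration <- function(x, ...) {
  tibble(locus_id = x$locus_id, bias = x$bias, n_points = x$n_points,
         residual_sd = x$residual_sd)
}

#' Remove the calibrated signal bias from a raw allelic ratio
#'
#' @param raw_ratio Positive observed height ratio(s), allele1/allele2.
#' @param curve An `ase_calibration`.
#' @return `raw_ratio / bias`.
#' @export
correct_ratio <- function(raw_ratio, curve) {
  stopifnot(inherits(curve, "ase_calibration"))
  if (any(!is.finite(raw_ratio) | raw_ratio <= 0)) {
    abort("raw_ratio must be positive")
  }
  raw_ratio / curve$bias
}

#' Calibration diagnostic plot
#'
#' Observed versus known ratios of a standard series on log axes, with the
#' fitted bias line.
#'
#' @param standards Calibration records for one locus.
#' @param curve Optional pre-fitted `ase_calibration` (refitted otherwise).
#' @return A ggplot object.
#' @export
plot_calibration <- function(standards, curve = fit_calibration(standards)) {
  df <- standards |>
    mutate(observed = .data$height_allele1 / .data$height_allele2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$known_ratio, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = log10(curve$bias),
                         linetype = 2, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "known molar ratio (allele1:allele2)",
                  y = "observed height ratio",
                  title = sprintf("%s calibration, bias %.3f",
                                  curve$locus_id, curve$bias))
}
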