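#' Aggregate TRPS technical replicates by the top-k rule
#'
#' Tunable resistive pulse sensing undercounts when the nanopore partially
#' clogs without tripping quality control, so technical replicates are biased
#' toward false negatives. The aggregation rule therefore takes the arithmetic
#' mean of the `k` highest replicate concentrations (default: the 3 highest).
#' With `k` equal to the number of replicates this is the plain mean.
#'
#' @param concentrations Numeric vector of particle concentrations
#'   (particles/mL) for the technical replicates of one biological replicate;
#'   all values must be positive.
#' @param k Number of top replicates to average (default 3).
#' @param fallback If `TRUE` and fewer than `k` replicates are supplied, fall
#'   back to the mean of all values with a warning instead of erroring.
#' @return The aggregated concentration (scalar).
#' @export
#' @examples
#' aggregate_trps(c(5, 9, 7, 3, 8))  # mean of 9, 8, 7 = 8
aggregate_trps <- function(concentrations, k = 3, fallback = FALSE) {
  if (!is.numeric(concentrations) || length(concentrations) == 0) {
    abort("`concentrations` must be a non-empty numeric vector.")
  }
  if (any(is.na(concentrations)) || any(concentrations <= 0)) {
    abort("all replicate concentrations must be positive.")
  }
  if (!is_count_scalar(k) || k < 1) abort("`k` must be a positive integer.")
  if (length(concentrations) < k) {
    if (!fallback) {
      abort(sprintf("need at least %d technical replicates, got %d.",
                    k, length(concentrations)))
    }
    warn(sprintf("only %d replicates available; averaging all of them.",
                 length(concentrations)))
    return(mean(concentrations))
  }
  mean(sort(concentrations, decreasing = TRUE)[seq_len(k)])
}

#' miRNA copies per vesicle
#'
#' Divides an absolute copy number (e.g. from ddPCR) by a particle count to
#' give average copies per extracellular vesicle.
#'
#' @param total_copies Total miRNA copies.
#' @param total_particles Total particle count; must be positive.
#' @return Copies per particle (scalar).
#' @export
#' @examples
#' copies_per_vesicle(3e9, 1e5)  # 30000 copies per vesicle
copies_per_vesicle <- function(total_copies, total_particles) {
  if (!is.numeric(total_copies) || total_copies < 0) {
    abort("`total_copies` must be non-negative.")
  }
  if (!is.numeric(total_particles) || total_particles <= 0) {
    abort("`total_particles` must be positive.")
  }
  total_copies / total_particles
}

#' Difference in per-vesicle copy load between two EV classes
#'
#' Convenience for comparing, e.g., large oncosomes (L-EV) against exosomes
#' (S-EV): copies per vesicle in class 1 minus copies per vesicle in class 2.
#'
#' @param copies_1,particles_1 Copy and particle totals for the first class.
#' @param copies_2,particles_2 Copy and particle totals for the second class.
#' @return The paired difference in copies per vesicle.
#' @export
copies_per_vesicle_diff <- function(copies_1, particles_1, copies_2, particles_2) {
  copies_per_vesicle(copies_1, particles_1) - copies_per_vesicle(copies_2, particles_2)
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of quantification cycle against log10 concentration over
#' a dilution series of known standards — the usual linear qPCR calibration
#' model. The amplification efficiency implied by the slope
#' (`10^(-1/slope) - 1`) is reported as a diagnostic but not used for
#' correction.
#'
#' @param points Data frame with columns `concentration` (known molar
#'   concentrations, strictly positive, at least 2 distinct values) and
#'   `cycle` (measured quantification-cycle values).
#' @return An object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `conc_range`, `cycle_range`,
#'   `fit` (the underlying `lm`), `points`.
#' @seealso [quantify()]
#' @export
#' @examples
#' std <- tibble::tibble(concentration = 10^seq(-18, -12),
#'                       cycle = 40 - 3.3219 * (seq(-18, -12) + 18))
#' curve <- fit_standard_curve(std)
#' quantify(curve, 36.6781)
fit_standard_curve <- function(points) {
  if (!is.data.frame(points) || !all(c("concentration", "cycle") %in% names(points))) {
    abort("`points` must have `concentration` and `cycle` columns.")
  }
  if (any(points$concentration <= 0)) {
    abort("standard concentrations must be strictly positive.")
  }
  if (length(unique(points$concentration)) < 2) {
    abort("at least 2 distinct standard concentrations are required.")
  }
  df <- tibble(log10_conc = log10(points$concentration), cycle = points$cycle)
  fit <- lm(cycle ~ log10_conc, data = df)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope == 0) abort("degenerate standard curve: zero slope.")
  r2 <- if (nrow(df) > 2) suppressWarnings(summary(fit)$r.squared) else 1
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      efficiency = 10^(-1 / slope) - 1,
      conc_range = range(points$concentration),
      cycle_range = range(predict(fit, tibble(log10_conc = log10(range(points$concentration))))),
      fit = fit,
      points = as_tibble(points)
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> cycle = %.4f %+.4f * log10(conc); R2 = %.4f, efficiency = %.1f%%\n",
              x$intercept, x$slope, x$r_squared, 100 * x$efficiency))
  cat(sprintf("  calibrated over [%.3g, %.3g] M\n", x$conc_range[1], x$conc_range[2]))
  invisible(x)
}

#' @describeIn fit_standard_curve Coefficient-level tidy output.
#' @param x,object A `standard_curve`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @describeIn fit_standard_curve One-row fit summary (slope, intercept, R2,
#'   efficiency, calibrated range).
#' @exportS3Method generics::glance
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         efficiency = x$efficiency,
         conc_min = x$conc_range[1], conc_max = x$conc_range[2],
         n = nrow(x$points))
}

#' @describeIn fit_standard_curve Calibration points and fitted line.
#' @exportS3Method ggplot2::autoplot
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(log10(.data$concentration), .data$cycle)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         linetype = "dashed") +
    ggplot2::labs(x = "log10 concentration (M)", y = "quantification cycle",
                  title = "qPCR standard curve") +
    ggplot2::theme_minimal()
}

#' Absolute quantification from a standard curve
#'
#' Inverts the fitted cycle-versus-log10-concentration line. Queries whose
#' implied concentration falls outside the calibrated range are returned but
#' flagged as extrapolated.
#'
#' @param curve A [fit_standard_curve()] object.
#' @param cycle Numeric vector of measured quantification-cycle values.
#' @return A tibble `cycle`, `concentration` (molar), `extrapolated`.
#' @export
quantify <- function(curve, cycle) {
  UseMethod("quantify")
}

#' @export
quantify.standard_curve <- function(curve, cycle) {
  if (!is.numeric(cycle)) abort("`cycle` must be numeric.")
  conc <- 10^((cycle - curve$intercept) / curve$slope)
  # small relative slack so queries exactly at the calibration endpoints are
  # not flagged by floating-point round-off
  lo <- curve$conc_range[1] * (1 - 1e-8)
  hi <- curve$conc_range[2] * (1 + 1e-8)
  tibble(
    cycle = cycle,
    concentration = conc,
    extrapolated = conc < lo | conc > hi
  )
}
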