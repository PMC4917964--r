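#' Albedo anchor tables
#'
#' An albedo anchor table holds average, minimum and maximum broadband albedo
#' (dimensionless fractions) for three surface states: dry clean winter snow
#' before the onset of melt (`dry_clean`), wet melting snow with no visible
#' algae (`wet_clean`), and snow carrying a full red-pigmented algal bloom
#' (`red`). The bands are oriented "in terms of decrease in albedo": within a
#' state the minimum-decrease band has the highest albedo, so
#' minimum >= average >= maximum.
#'
#' @param average,minimum,maximum numeric length-3 vectors of albedo fractions,
#'   ordered `dry_clean`, `wet_clean`, `red`.
#' @return A data frame of class `albedo_anchor_table` with a `state` column
#'   and one column per band.
#' @seealso [read_anchor_table()] for the tab-separated file format,
#'   [default_anchor_table()] for the packaged field values.
#' @export
albedo_anchor_table <- function(average, minimum, maximum) {
  states <- c("dry_clean", "wet_clean", "red")
  stopifnot(length(average) == 3L, length(minimum) == 3L, length(maximum) == 3L)
  tab <- data.frame(state = states, average = as.numeric(average),
                    minimum = as.numeric(minimum), maximum = as.numeric(maximum),
                    stringsAsFactors = FALSE)
  validate_anchor_table(tab)
}

validate_anchor_table <- function(tab) {
  required <- c("state", "average", "minimum", "maximum")
  if (!all(required %in% names(tab)))
    stop("anchor table needs columns: ", paste(required, collapse = ", "))
  states <- c("dry_clean", "wet_clean", "red")
  missing <- setdiff(states, tab$state)
  if (length(missing) > 0L)
    stop("anchor table missing surface state(s): ", paste(missing, collapse = ", "))
  tab <- tab[match(states, tab$state), required]
  rownames(tab) <- NULL
  vals <- as.matrix(tab[, c("average", "minimum", "maximum")])
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("all albedo values must be finite fractions in [0, 1]")
  # band orientation: minimum decrease >= average >= maximum decrease
  if (any(tab$minimum < tab$average - 1e-12) || any(tab$average < tab$maximum - 1e-12))
    stop("within each state, minimum >= average >= maximum albedo is required")
  # melt/bloom darkening: dry >= wet >= red in every band
  for (band in c("average", "minimum", "maximum")) {
    v <- tab[[band]]
    if (v[1] < v[2] - 1e-12 || v[2] < v[3] - 1e-12)
      stop("per band, dry_clean >= wet_clean >= red albedo is required (band: ", band, ")")
  }
  class(tab) <- c("albedo_anchor_table", "data.frame")
  tab
}

#' Read or materialize an albedo anchor table
#'
#' `read_anchor_table()` reads a tab-separated file with columns
#' `state`, `average`, `minimum`, `maximum` and states
#' `dry_clean`/`wet_clean`/`red`. `default_anchor_table()` returns the
#' packaged field table (dry clean snow 0.90/0.95/0.85, wet clean snow
#' 0.75/0.80/0.70, red snow 0.65/0.77/0.53).
#'
#' @param path path to a tab-separated anchor file.
#' @return An `albedo_anchor_table`.
#' @export
read_anchor_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_anchor_table(tab)
}

#' @rdname read_anchor_table
#' @export
default_anchor_table <- function() {
  read_anchor_table(system.file("extdata", "albedo_anchors.tsv",
                                package = "redsnow", mustWork = TRUE))
}

anchor_value <- function(table, state, band) {
  row <- table[table$state == state, , drop = FALSE]
  if (nrow(row) != 1L) stop("surface state not found in anchor table: ", state)
  row[[band]]
}

new_anchor_series <- function(day, albedo, label) {
  if (length(day) < 2L) stop("an anchor series needs at least 2 points")
  if (day[1] != 0) stop("anchor series must start at day 0")
  if (any(diff(day) <= 0)) stop("anchor days must be strictly increasing")
  structure(data.frame(day = day, albedo = albedo),
            label = label, class = c("anchor_series", "data.frame"))
}

#' Build albedo anchor series for the two melt-season scenarios
#'
#' Scenario `"clean"` is the physical benchmark: dry clean snow (day 0, state
#' average) becoming a wet melting surface at its minimum-decrease albedo
#' after 25 days, its average after 50 days and its maximum-decrease value
#' after 100 days. Scenario `"red"` follows the same template through the red
#' snow row: a light bloom after 25 days and a fully developed dark-red bloom
#' by day 100.
#'
#' @param table an [albedo_anchor_table()].
#' @param scenario `"clean"` or `"red"`.
#' @return An `anchor_series` data frame with `day` and `albedo` columns.
#' @examples
#' build_scenario_anchors(default_anchor_table(), "red")
#' @export
build_scenario_anchors <- function(table, scenario = c("clean", "red")) {
  scenario <- match.arg(scenario)
  state <- if (scenario == "clean") "wet_clean" else "red"
  new_anchor_series(
    day = c(0, 25, 50, 100),
    albedo = c(anchor_value(table, "dry_clean", "average"),
               anchor_value(table, state, "minimum"),
               anchor_value(table, state, "average"),
               anchor_value(table, state, "maximum")),
    label = scenario)
}

#' Build a single-band anchor series for the sensitivity analysis
#'
#' Tracks one band (average, minimum or maximum decrease) through the three
#' surface states, anchored at days 0 (dry), 50 (wet) and 100 (red). Fitting
#' the three band curves and differencing adjacent pairs gives the
#' sensitivity range around the main scenario difference.
#'
#' @inheritParams build_scenario_anchors
#' @param band `"average"`, `"minimum"` or `"maximum"`.
#' @return An `anchor_series`.
#' @export
build_band_anchors <- function(table, band = c("average", "minimum", "maximum")) {
  band <- match.arg(band)
  new_anchor_series(
    day = c(0, 50, 100),
    albedo = c(anchor_value(table, "dry_clean", band),
               anchor_value(table, "wet_clean", band),
               anchor_value(table, "red", band)),
    label = paste0("band_", band))
}

#' Fit a square-root-of-time albedo decay curve
#'
#' Fits `alpha(t) = a - b * sqrt(t)` by ordinary least squares of albedo on
#' the square root of day, including the day-0 anchor. The square-root form
#' comes from a one-dimensional moving-boundary treatment of the melting
#' surface: the surface retreats while its albedo evolves, and the anchor
#' values follow a square-root dependence on time.
#'
#' @param series an `anchor_series` (or any data frame with `day` and
#'   `albedo` columns).
#' @return An object of class `sqrt_decay_fit`: list with intercept `a`
#'   (albedo fraction), decay coefficient `b` (albedo per sqrt(day)),
#'   residual sum of squares `rss`, anchor count `n`, and `fitted`/`residuals`.
#' @examples
#' fit_sqrt_decay(build_scenario_anchors(default_anchor_table(), "clean"))
#' @export
fit_sqrt_decay <- function(series) {
  day <- series$day
  albedo <- series$albedo
  if (length(day) < 2L) stop("need at least 2 anchors to fit")
  x <- sqrt(day)
  if (diff(range(x)) < .Machine$double.eps^0.5)
    stop("singular fit: all sqrt(day) abscissae identical")
  fit <- stats::lm(albedo ~ x)
  res <- stats::residuals(fit)
  structure(list(a = unname(stats::coef(fit)[1]),
                 b = -unname(stats::coef(fit)[2]),
                 rss = sum(res^2), n = length(day),
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(res),
                 label = attr(series, "label", exact = TRUE)),
            class = "sqrt_decay_fit")
}

#' Predicted albedo from a square-root decay fit
#'
#' @param object a `sqrt_decay_fit`.
#' @param t days (non-negative, vectorized).
#' @param ... unused.
#' @return Predicted albedo `a - b*sqrt(t)`.
#' @export
predict.sqrt_decay_fit <- function(object, t, ...) {
  stopifnot(all(t >= 0))
  object$a - object$b * sqrt(t)
}

#' @export
print.sqrt_decay_fit <- function(x, ...) {
  cat(sprintf("sqrt-decay fit%s: alpha(t) = %.5f - %.5f*sqrt(t)  (n = %d anchors, rss = %.3g)\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$a, x$b, x$n, x$rss))
  invisible(x)
}

#' Integrate an albedo decay curve over a melt season
#'
#' Closed-form integral of `alpha(t) = a - b*sqrt(t)` from 0 to `horizon`:
#' `a*T - (2/3)*b*T^1.5`, in albedo-days. Over a 100-day horizon the value
#' divided by the horizon is the season-mean albedo.
#'
#' @param fit a `sqrt_decay_fit`.
#' @param horizon season length in days, `>= 0`.
#' @return Integrated albedo (albedo-days).
#' @export
integrate_albedo <- function(fit, horizon) {
  if (length(horizon) != 1L || !is.finite(horizon) || horizon < 0)
    stop("horizon must be a single non-negative number of days")
  fit$a * horizon - (2 / 3) * fit$b * horizon^1.5
}

#' Difference two integrated albedo curves
#'
#' Given two square-root decay fits, forms the magnitude of the linear term
#' `|a2 - a1| * T` and of the three-halves term `(2/3) * |b2 - b1| * T^1.5`,
#' then combines them by the stated convention: `"sum"` adds the magnitudes
#' (the main scenario comparison), `"difference"` subtracts the curvature
#' term from the linear term (the sensitivity arithmetic). Both conventions
#' are preserved deliberately; see the methods vignette.
#'
#' @param fit1,fit2 `sqrt_decay_fit` objects (reference and perturbed curve).
#' @param horizon season length in days, `> 0`.
#' @param convention `"sum"` or `"difference"`.
#' @return An `integrated_difference`: list with `term_a`, `term_b`,
#'   `combined` (albedo-days), `coef_a` = |a2-a1|, `coef_b` = (2/3)|b2-b1|,
#'   `horizon` and `convention`.
#' @export
scenario_difference <- function(fit1, fit2, horizon = 100,
                                convention = c("sum", "difference")) {
  convention <- match.arg(convention)
  if (length(horizon) != 1L || !is.finite(horizon) || horizon <= 0)
    stop("horizon must be a single positive number of days")
  coef_a <- abs(fit2$a - fit1$a)
  coef_b <- (2 / 3) * abs(fit2$b - fit1$b)
  term_a <- coef_a * horizon
  term_b <- coef_b * horizon^1.5
  combined <- if (convention == "sum") term_a + term_b else term_a - term_b
  structure(list(term_a = term_a, term_b = term_b, combined = combined,
                 coef_a = coef_a, coef_b = coef_b,
                 horizon = horizon, convention = convention),
            class = "integrated_difference")
}

#' Sensitivity analysis over the anchor-table bands
#'
#' Fits band curves to the minimum, average and maximum columns of the
#' anchor table (anchored at days 0/50/100) and differences adjacent bands
#' under the `"difference"` convention, giving the spread of the integrated
#' albedo change attributable to the measurement bands.
#'
#' @inheritParams build_scenario_anchors
#' @param horizon season length in days.
#' @return List with `min_vs_avg` and `avg_vs_max` (`integrated_difference`
#'   objects), the three band fits, and `range_magnitude`: the shared
#'   one-decimal magnitude of the two combined values.
#' @export
sensitivity_analysis <- function(table, horizon = 100) {
  fits <- lapply(c(minimum = "minimum", average = "average", maximum = "maximum"),
                 function(b) fit_sqrt_decay(build_band_anchors(table, b)))
  min_vs_avg <- scenario_difference(fits$minimum, fits$average, horizon, "difference")
  avg_vs_max <- scenario_difference(fits$average, fits$maximum, horizon, "difference")
  mags <- round(abs(c(min_vs_avg$combined, avg_vs_max$combined)), 1)
  list(min_vs_avg = min_vs_avg, avg_vs_max = avg_vs_max, fits = fits,
       range_magnitude = if (mags[1] == mags[2]) mags[1] else mean(mags))
}

#' Full integrated bio-albedo change report
#'
#' Runs both melt-season scenarios (clean benchmark vs red-snow bloom) through
#' the square-root decay fit, integrates each over the horizon, forms their
#' difference under the `"sum"` convention, and appends the band sensitivity
#' analysis. Over a 100-day horizon the combined value in albedo-days is
#' numerically equal to the mean albedo difference expressed in percentage
#' points, which is how the headline integer percent is read.
#'
#' @inheritParams build_scenario_anchors
#' @param horizon season length in days (default 100: a conservative season
#'   encompassing the June-August measurement window).
#' @return List of class `albedo_report` with the fits, per-scenario
#'   integrals, the scenario `difference`, `headline_percent` (integer), and
#'   `sensitivity` (including its one-decimal range magnitude).
#' @examples
#' rep <- integrated_albedo_report(default_anchor_table())
#' rep$headline_percent
#' @export
integrated_albedo_report <- function(table, horizon = 100) {
  clean_fit <- fit_sqrt_decay(build_scenario_anchors(table, "clean"))
  red_fit <- fit_sqrt_decay(build_scenario_anchors(table, "red"))
  diff <- scenario_difference(clean_fit, red_fit, horizon, "sum")
  sens <- sensitivity_analysis(table, horizon)
  structure(list(
    horizon = horizon,
    clean_fit = clean_fit, red_fit = red_fit,
    clean_integral = integrate_albedo(clean_fit, horizon),
    red_integral = integrate_albedo(red_fit, horizon),
    difference = diff,
    term_a = round(diff$term_a, 2),
    term_b = round(diff$term_b, 2),
    combined = round(diff$combined, 2),
    headline_percent = round(diff$combined),
    sensitivity = sens,
    note = paste("Over a 100-day horizon, albedo-days numerically equal the",
                 "mean albedo difference in percentage points.")),
    class = "albedo_report")
}

#' @export
print.albedo_report <- function(x, ...) {
  cat("Integrated bio-albedo change report\n")
  cat(sprintf("  horizon           = %g days\n", x$horizon))
  cat(sprintf("  clean fit         : a = %.5f, b = %.5f\n", x$clean_fit$a, x$clean_fit$b))
  cat(sprintf("  red fit           : a = %.5f, b = %.5f\n", x$red_fit$a, x$red_fit$b))
  cat(sprintf("  linear term       = %.2f albedo-days\n", x$term_a))
  cat(sprintf("  t^1.5 term        = %.2f albedo-days\n", x$term_b))
  cat(sprintf("  combined          = %.2f albedo-days\n", x$combined))
  cat(sprintf("  headline          = %d%%\n", x$headline_percent))
  cat(sprintf("  sensitivity coeffs: |da| = %.4f, (2/3)|db| = %.4f\n",
              x$sensitivity$min_vs_avg$coef_a, x$sensitivity$min_vs_avg$coef_b))
  cat(sprintf("  sensitivity range = ~%.1f about the mean\n",
              x$sensitivity$range_magnitude))
  invisible(x)
}

#' Serialize an albedo report
#'
#' Writes the report both as machine-readable JSON and as flat `key=value`
#' text; the two carry numerically identical values.
#'
#' @param report an `albedo_report`.
#' @param json_path,text_path output file paths (either may be `NULL`).
#' @return The flat named list of report values, invisibly.
#' @export
write_albedo_report <- function(report, json_path = NULL, text_path = NULL) {
  flat <- list(
    horizon = report$horizon,
    clean_a = report$clean_fit$a, clean_b = report$clean_fit$b,
    red_a = report$red_fit$a, red_b = report$red_fit$b,
    clean_integral = report$clean_integral,
    red_integral = report$red_integral,
    term_a = report$term_a, term_b = report$term_b,
    combined = report$combined,
    headline_percent = report$headline_percent,
    sens_coef_a = report$sensitivity$min_vs_avg$coef_a,
    sens_coef_b = report$sensitivity$min_vs_avg$coef_b,
    sens_min_vs_avg = report$sensitivity$min_vs_avg$combined,
    sens_avg_vs_max = report$sensitivity$avg_vs_max$combined,
    sens_range = report$sensitivity$range_magnitude)
  if (!is.null(json_path))
    jsonlite::write_json(flat, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(text_path))
    writeLines(sprintf("%s=%.10g", names(flat), unlist(flat)), text_path)
  invisible(flat)
}

#' Reproduce the packaged anchor-table worked example
#'
#' Convenience wrapper: runs [integrated_albedo_report()] on the packaged
#' field anchor table at the default 100-day horizon.
#'
#' @inheritParams integrated_albedo_report
#' @return An `albedo_report`.
#' @export
reproduce_table1 <- function(horizon = 100) {
  integrated_albedo_report(default_anchor_table(), horizon)
}
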