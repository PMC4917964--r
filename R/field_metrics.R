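#' Surface albedo from paired radiometer readings
#'
#' Albedo is the ratio of the mean of five reflected-radiation readings to
#' the mean of five incident-radiation readings (broadband, any consistent
#' units). Each reading set also carries a quality-control flag: the set
#' passes when the coefficient of variation of both the incident and the
#' reflected readings is below the threshold (default 10% of the mean).
#' Failing sites are flagged, not dropped.
#'
#' @param incident,reflected numeric vectors of 5 positive readings each.
#' @param qc_threshold coefficient-of-variation threshold as a fraction
#'   (default 0.10).
#' @return List with `albedo` (fraction), `qc_pass` (logical), and the two
#'   coefficients of variation `cv_incident`, `cv_reflected`.
#' @examples
#' compute_albedo(rep(1000, 5), rep(650, 5))
#' @export
compute_albedo <- function(incident, reflected, qc_threshold = 0.10) {
  if (length(incident) != 5L || length(reflected) != 5L)
    stop("expected exactly 5 incident and 5 reflected readings")
  if (any(!is.finite(incident)) || any(incident <= 0))
    stop("incident readings must be positive")
  if (any(!is.finite(reflected)) || any(reflected <= 0))
    stop("reflected readings must be positive")
  cv <- function(x) stats::sd(x) / mean(x)
  cv_i <- cv(incident)
  cv_r <- cv(reflected)
  list(albedo = mean(reflected) / mean(incident),
       qc_pass = cv_i < qc_threshold && cv_r < qc_threshold,
       cv_incident = cv_i, cv_reflected = cv_r)
}

#' Spherical cell volume from diameter
#'
#' Snow-algal cells (and their resting cysts) are treated as perfect spheres:
#' `V = (4/3) * pi * r^3` with `r = diameter / 2`.
#'
#' @param diameter cell diameter in micrometres (vectorized, `> 0`).
#' @return Cell volume in cubic micrometres.
#' @examples
#' cell_volume(20) # ~4188.79
#' @export
cell_volume <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("cell diameters must be positive")
  (4 / 3) * pi * (diameter / 2)^3
}

#' Total algal biomass as biovolume concentration
#'
#' The mean of the per-cell volumes (not the volume of the mean diameter —
#' the two differ for any spread of diameters) multiplied by the cell
#' concentration.
#'
#' @param diameters measured cell diameters in micrometres (typically 100
#'   per sample).
#' @param concentration cells per millilitre, `>= 0`.
#' @return Biovolume in cubic micrometres per millilitre.
#' @export
total_biomass <- function(diameters, concentration) {
  if (length(diameters) < 1L) stop("at least one cell diameter is required")
  if (length(concentration) != 1L || !is.finite(concentration) || concentration < 0)
    stop("concentration must be a single non-negative number")
  mean(cell_volume(diameters)) * concentration
}

#' Pearson correlation with a two-sided t-test
#'
#' Pearson's r between paired site measurements, with a two-sided p-value
#' from the t transformation `t = r * sqrt((n-2) / (1-r^2))` on `n-2`
#' degrees of freedom. No multiple-testing correction is applied here.
#'
#' @param x,y paired numeric vectors of equal length, `n >= 3`, each with
#'   non-zero variance.
#' @return List of class `correlation_result`: `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, P = %.4g (n = %d)\n", x$r, x$p, x$n))
  invisible(x)
}

#' Per-site field metrics from a site table
#'
#' Applies [compute_albedo()] and [total_biomass()] to every row of a site
#' table (as produced by the synthetic-study generator or read from a
#' tab-separated field sheet) and tests the biomass-albedo association.
#'
#' @param sites data frame with columns `incident_1..5`, `reflected_1..5`,
#'   `cell_conc` (cells/ml), `mean_cell_volume` (um^3) or `mean_diameter`
#'   (um), and `location`.
#' @param qc_threshold passed to [compute_albedo()].
#' @param locations optional subset of location labels used for the
#'   biomass-albedo correlation (default: all sites).
#' @return List with the augmented `sites` table (columns `albedo`,
#'   `qc_pass`, `biomass`) and `biomass_albedo` (a `correlation_result`).
#' @export
field_metrics <- function(sites, qc_threshold = 0.10, locations = NULL) {
  inc <- as.matrix(sites[, paste0("incident_", 1:5)])
  ref <- as.matrix(sites[, paste0("reflected_", 1:5)])
  res <- lapply(seq_len(nrow(sites)), function(i)
    compute_albedo(inc[i, ], ref[i, ], qc_threshold))
  sites$albedo <- vapply(res, `[[`, numeric(1), "albedo")
  sites$qc_pass <- vapply(res, `[[`, logical(1), "qc_pass")
  mv <- if ("mean_cell_volume" %in% names(sites)) sites$mean_cell_volume
        else cell_volume(sites$mean_diameter)
  sites$biomass <- mv * sites$cell_conc
  keep <- if (is.null(locations)) rep(TRUE, nrow(sites))
          else sites$location %in% locations
  list(sites = sites,
       biomass_albedo = pearson_test(sites$biomass[keep], sites$albedo[keep]))
}
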