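#' Configuration for a synthetic red-snow study
#'
#' Defaults emulate a 40-site Arctic survey across four locations —
#' Svalbard (`SVA`, 12 sites), Northern Sweden/Tarfala (`TAR`, 24),
#' Greenland/Mittivakkat (`MIT`, 2) and Iceland (`ICE`, 2) — with:
#' location-invariant algal species composition (six taxa, dominant
#' uncultured Chlamydomonadaceae sp. 2 around 55%), location-specific
#' bacterial class composition (Sphingobacteria dominant in `TAR`,
#' Saprospirae/Cytophagia/Betaproteobacteria/Synechococcophycideae in
#' `SVA`, Sphingobacteria + Saprospirae in `MIT`,
#' Saprospirae/Alpha-/Betaproteobacteria in `ICE`), geochemical
#' fold-differences (DOC about 5x higher in `TAR` than `SVA`, easily
#' leachable elements about 10x higher in `SVA` than `TAR`, iron about
#' 100x higher in `ICE`, nitrate and phosphate location-invariant), cell
#' concentrations log-uniform on 10^3–10^4 cells/ml, and surface albedo in
#' [0.50, 0.75] negatively coupled to algal biovolume.
#'
#' @param locations named integer vector of sites per location.
#' @param algal_means named algal species proportions (sum to 1; shared by
#'   all locations).
#' @param algal_concentration Dirichlet precision of the algal draws.
#' @param bacterial_means location x class matrix of bacterial class
#'   proportions (rows sum to 1).
#' @param bacterial_concentration Dirichlet precision of the bacterial
#'   draws.
#' @param sphingo_doc_gamma exponent coupling the Sphingobacteria Dirichlet
#'   mean to a site's DOC relative to its location median (>= 0).
#' @param geochem_vars named list, one entry per geochemical variable, each
#'   with `meanlog` (named per location, log of the location median) and a
#'   shared `sdlog`.
#' @param cell_conc_range cells/ml range for the log-uniform draw.
#' @param diameter_mean,diameter_site_sd,diameter_cell_sd,n_diameters cell
#'   diameter model (um): site means are normal around `diameter_mean`,
#'   individual cells normal around the site mean.
#' @param albedo_intercept,albedo_slope,albedo_noise_sd linear
#'   biomass-albedo coupling: true albedo =
#'   intercept + slope * biovolume + N(0, noise), clipped to `albedo_range`.
#'   The default noise is calibrated once so the recovered Pearson r at the
#'   Svalbard+Sweden scale (n = 36) has median near -0.65.
#' @param albedo_range clipping range for true albedo.
#' @param incident_mean,reading_cv radiometer model: per-site incident
#'   irradiance level (arbitrary consistent units) and per-reading
#'   coefficient of variation.
#' @param library_size_range per-sample sequencing depth range (uniform
#'   integer draw), exercising rarefaction downstream.
#' @param otus_per_taxon number of OTUs each taxon's proportion is split
#'   across (exercises rank aggregation).
#' @return A list of class `study_config`.
#' @export
study_config <- function(
    locations = c(SVA = 12L, TAR = 24L, MIT = 2L, ICE = 2L),
    algal_means = c(Chlamydomonadaceae_sp_2 = 0.55,
                    Chloromonas_polyptera = 0.18,
                    Chloromonas_nivalis = 0.08,
                    Chloromonas_alpina = 0.005,
                    Chlamydomonadaceae_sp_1 = 0.065,
                    Raphidonema_sempervirens = 0.12),
    algal_concentration = 120,
    bacterial_means = default_bacterial_means(),
    bacterial_concentration = 60,
    sphingo_doc_gamma = 0.4,
    geochem_vars = default_geochem_vars(),
    cell_conc_range = c(1e3, 1e4),
    diameter_mean = 15, diameter_site_sd = 1.5, diameter_cell_sd = 2.5,
    n_diameters = 100L,
    albedo_intercept = 0.76, albedo_slope = -1.3e-8,
    albedo_noise_sd = 0.08,
    albedo_range = c(0.50, 0.75),
    incident_mean = 1500, reading_cv = 0.03,
    library_size_range = c(5000L, 15000L),
    otus_per_taxon = 3L) {
  if (any(locations < 1L)) stop("every location needs at least one site")
  if (abs(sum(algal_means) - 1) > 1e-8)
    stop("algal composition means must sum to 1")
  if (any(abs(rowSums(bacterial_means) - 1) > 1e-8))
    stop("bacterial composition means must sum to 1 per location")
  if (!all(names(locations) %in% rownames(bacterial_means)))
    stop("every location label needs a row in bacterial_means")
  for (v in geochem_vars)
    if (any(!is.finite(v$meanlog)) || !is.finite(v$sdlog) || v$sdlog < 0)
      stop("geochemistry parameters must be finite (sdlog >= 0)")
  if (albedo_slope > 0) stop("biomass-albedo coupling slope must be <= 0")
  structure(as.list(environment()), class = "study_config")
}

#' Default bacterial class means per location
#'
#' @return Location x class proportion matrix (rows sum to 1).
#' @export
default_bacterial_means <- function() {
  classes <- c("Sphingobacteria", "Saprospirae", "Cytophagia",
               "Alphaproteobacteria", "Betaproteobacteria",
               "Synechococcophycideae", "Other")
  m <- rbind(
    SVA = c(0.05, 0.25, 0.15, 0.08, 0.19, 0.13, 0.15),
    TAR = c(0.40, 0.12, 0.05, 0.13, 0.10, 0.05, 0.15),
    MIT = c(0.29, 0.28, 0.05, 0.10, 0.08, 0.05, 0.15),
    ICE = c(0.05, 0.25, 0.05, 0.25, 0.20, 0.05, 0.15))
  colnames(m) <- classes
  m
}

#' Default geochemistry model
#'
#' Lognormal per-location medians (on the log scale) encoding the
#' fold-difference structure: DOC 5x higher in `TAR` than `SVA`, total
#' particulate carbon 2.5x, leachable elements 10x higher in `SVA`, iron
#' 100x higher in `ICE`, nitrate and phosphate flat across locations.
#' Units: mg/l equivalents; only ratios matter downstream.
#'
#' @return Named list of `list(meanlog =, sdlog =)` per variable.
#' @export
default_geochem_vars <- function() {
  loc <- c("SVA", "TAR", "MIT", "ICE")
  lvl <- function(v) stats::setNames(log(v), loc)
  list(
    DOC = list(meanlog = lvl(c(1.0, 5.0, 1.5, 1.5)), sdlog = 0.25),
    TC = list(meanlog = lvl(c(2.0, 5.0, 2.5, 2.5)), sdlog = 0.25),
    leachable = list(meanlog = lvl(c(10, 1, 2, 2)), sdlog = 0.25),
    Fe = list(meanlog = lvl(c(0.05, 0.05, 0.05, 5.0)), sdlog = 0.25),
    NO3 = list(meanlog = lvl(c(0.1, 0.1, 0.1, 0.1)), sdlog = 0.25),
    PO4 = list(meanlog = lvl(c(0.02, 0.02, 0.02, 0.02)), sdlog = 0.25))
}

# Dirichlet draws via normalized gamma variates; alpha = mean * concentration.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  sweep(g, 1, rowSums(g), "/")
}

site_locations <- function(config) {
  rep(names(config$locations), times = config$locations)
}

maybe_seeded <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Generate location-invariant algal species proportions
#'
#' One Dirichlet draw per site around the shared (location-invariant)
#' species means, so that algal composition is statistically exchangeable
#' across locations — the cosmopolitan-algae half of the study design.
#'
#' @param config a [study_config()].
#' @param seed optional integer seed (`NULL`: use the current RNG state).
#' @return Sites x species proportion matrix (rows sum to 1).
#' @export
generate_algal_composition <- function(config, seed = NULL) {
  n <- sum(config$locations)
  maybe_seeded(seed, {
    p <- rdirichlet(n, config$algal_means * config$algal_concentration)
    dimnames(p) <- list(NULL, names(config$algal_means))
    p
  })
}

#' Generate location-specific bacterial class proportions
#'
#' One Dirichlet draw per site around its location's class means; the
#' Sphingobacteria mean is additionally tilted by the site's DOC relative
#' to its location median (exponent `sphingo_doc_gamma`), encoding the
#' positive Sphingobacteria-carbon association.
#'
#' @inheritParams generate_algal_composition
#' @param doc optional per-site DOC vector enabling the carbon coupling.
#' @return Sites x class proportion matrix (rows sum to 1).
#' @export
generate_bacterial_composition <- function(config, doc = NULL, seed = NULL) {
  locs <- site_locations(config)
  means <- config$bacterial_means[locs, , drop = FALSE]
  if (!is.null(doc) && config$sphingo_doc_gamma > 0 &&
      "Sphingobacteria" %in% colnames(means)) {
    loc_med <- exp(config$geochem_vars$DOC$meanlog[locs])
    tilt <- (doc / loc_med)^config$sphingo_doc_gamma
    means[, "Sphingobacteria"] <- means[, "Sphingobacteria"] * tilt
    means <- sweep(means, 1, rowSums(means), "/")
  }
  maybe_seeded(seed, {
    p <- t(vapply(seq_len(nrow(means)), function(i)
      rdirichlet(1, means[i, ] * config$bacterial_concentration)[1, ],
      numeric(ncol(means))))
    dimnames(p) <- list(NULL, colnames(means))
    p
  })
}

#' Generate per-site geochemistry
#'
#' Independent lognormal draws per variable with location-specific medians
#' (see [default_geochem_vars()]).
#'
#' @inheritParams generate_algal_composition
#' @return Data frame, one row per site, one column per variable.
#' @export
generate_geochemistry <- function(config, seed = NULL) {
  locs <- site_locations(config)
  maybe_seeded(seed, {
    out <- lapply(config$geochem_vars, function(v)
      stats::rlnorm(length(locs), meanlog = v$meanlog[locs], sdlog = v$sdlog))
    as.data.frame(out)
  })
}

#' Generate per-site cell data and radiometer readings
#'
#' Cell concentrations are log-uniform on the configured range; per-site
#' mean cell volume comes from `n_diameters` simulated diameter
#' measurements; true albedo is the linear biomass coupling plus Gaussian
#' noise, clipped to the configured range. Radiometer reading sets are
#' synthesized with per-reading jitter but rescaled so the ratio of means
#' returns the true albedo exactly, and they pass the 10% coefficient-of-
#' variation quality control by construction.
#'
#' @inheritParams generate_algal_composition
#' @return Data frame with columns `cell_conc`, `mean_diameter`,
#'   `mean_cell_volume`, `biomass`, `albedo_true`, `incident_1..5`,
#'   `reflected_1..5`.
#' @export
generate_field_measurements <- function(config, seed = NULL) {
  n <- sum(config$locations)
  maybe_seeded(seed, {
    conc <- 10^stats::runif(n, log10(config$cell_conc_range[1]),
                            log10(config$cell_conc_range[2]))
    site_d <- stats::rnorm(n, config$diameter_mean, config$diameter_site_sd)
    mcv <- numeric(n)
    mean_d <- numeric(n)
    for (i in seq_len(n)) {
      d <- stats::rnorm(config$n_diameters, site_d[i], config$diameter_cell_sd)
      d <- pmax(d, 1)  # guard: diameters are physical lengths
      mean_d[i] <- mean(d)
      mcv[i] <- mean(cell_volume(d))
    }
    biomass <- mcv * conc
    raw <- config$albedo_intercept + config$albedo_slope * biomass +
      stats::rnorm(n, 0, config$albedo_noise_sd)
    unphysical <- mean(raw < 0 | raw > 1)
    if (unphysical > 0.05)
      warning(sprintf("albedo coupling leaves [0, 1] pre-clip for %.0f%% of sites; check config",
                      100 * unphysical))
    albedo <- pmin(pmax(raw, config$albedo_range[1]), config$albedo_range[2])
    inc <- matrix(NA_real_, n, 5)
    ref <- matrix(NA_real_, n, 5)
    for (i in seq_len(n)) {
      base <- stats::rnorm(1, config$incident_mean, 0.05 * config$incident_mean)
      ii <- base * (1 + stats::rnorm(5, 0, config$reading_cv))
      rr <- albedo[i] * base * (1 + stats::rnorm(5, 0, config$reading_cv))
      rr <- rr * (albedo[i] * mean(ii)) / mean(rr)  # pin the ratio of means
      inc[i, ] <- ii
      ref[i, ] <- rr
    }
    colnames(inc) <- paste0("incident_", 1:5)
    colnames(ref) <- paste0("reflected_", 1:5)
    data.frame(cell_conc = conc, mean_diameter = mean_d,
               mean_cell_volume = mcv, biomass = biomass,
               albedo_true = albedo, inc, ref)
  })
}

#' Multinomial counts from proportions
#'
#' One multinomial draw per sample at the given library size, emulating
#' sequencing-depth variation on top of the true compositions.
#'
#' @param proportions samples x taxa proportion matrix (rows sum to 1).
#' @param library_size integer vector (recycled) of reads per sample.
#' @param seed optional integer seed.
#' @return Samples x taxa count matrix; row sums equal `library_size`.
#' @export
counts_from_proportions <- function(proportions, library_size, seed = NULL) {
  if (any(abs(rowSums(proportions) - 1) > 1e-6))
    stop("proportions must sum to 1 per sample")
  if (any(library_size < 1)) stop("library sizes must be >= 1")
  library_size <- rep_len(library_size, nrow(proportions))
  maybe_seeded(seed, {
    counts <- t(vapply(seq_len(nrow(proportions)), function(i)
      as.numeric(stats::rmultinom(1, library_size[i], proportions[i, ])),
      numeric(ncol(proportions))))
    dimnames(counts) <- dimnames(proportions)
    counts
  })
}

# Split each taxon's proportion across k OTUs with fixed uneven weights so
# rank aggregation is exercised; weights are deterministic (not drawn) to
# keep the per-taxon totals exactly the generated proportions.
split_taxa_to_otus <- function(proportions, k) {
  if (k <= 1L) return(proportions)
  w <- 2^(seq_len(k) - 1)
  w <- w / sum(w)
  cols <- lapply(seq_len(ncol(proportions)), function(j)
    outer(proportions[, j], w))
  out <- do.call(cbind, cols)
  colnames(out) <- unlist(lapply(colnames(proportions), function(nm)
    paste0(nm, "_OTU", seq_len(k))))
  out
}

algal_taxonomy <- function(species, otus_per_taxon) {
  lineages <- paste0("k__Eukaryota; p__Chlorophyta; c__Chlorophyceae; ",
                     "o__Chlamydomonadales; f__Chlamydomonadaceae; g__; s__",
                     species)
  rep(lineages, each = otus_per_taxon)
}

bacterial_taxonomy <- function(classes, otus_per_taxon) {
  phylum <- c(Sphingobacteria = "Bacteroidetes", Saprospirae = "Bacteroidetes",
              Cytophagia = "Bacteroidetes",
              Alphaproteobacteria = "Proteobacteria",
              Betaproteobacteria = "Proteobacteria",
              Synechococcophycideae = "Cyanobacteria")
  ph <- ifelse(classes %in% names(phylum), phylum[classes], "")
  lineages <- ifelse(classes == "Other", "k__Bacteria",
                     paste0("k__Bacteria; p__", ph, "; c__", classes))
  rep(lineages, each = otus_per_taxon)
}

#' Simulate a complete synthetic red-snow study
#'
#' Draws geochemistry, algal and bacterial compositions (with the
#' DOC-Sphingobacteria coupling), field measurements, and multinomial OTU
#' counts at varying library sizes, assembling everything into one
#' `snow_study` object. Fully deterministic given `config` and `seed`.
#'
#' @param config a [study_config()].
#' @param seed integer root seed for the whole study.
#' @return A list of class `snow_study`: `algal` and `bacterial`
#'   [otu_table()]s, a `sites` data frame (location, geochemistry,
#'   radiometer readings, cell data), `config` and `seed`.
#' @examples
#' st <- simulate_study(study_config(), seed = 1)
#' st$bacterial
#' @export
simulate_study <- function(config = study_config(), seed = 1L) {
  withr::with_seed(seed, {
    locs <- site_locations(config)
    n <- length(locs)
    ids <- sprintf("S%02d", seq_len(n))
    geochem <- generate_geochemistry(config)
    algal_p <- generate_algal_composition(config)
    bact_p <- generate_bacterial_composition(config, doc = geochem$DOC)
    field <- generate_field_measurements(config)
    ls_a <- sample(config$library_size_range[1]:config$library_size_range[2], n,
                   replace = TRUE)
    ls_b <- sample(config$library_size_range[1]:config$library_size_range[2], n,
                   replace = TRUE)
    k <- config$otus_per_taxon
    algal_counts <- counts_from_proportions(split_taxa_to_otus(algal_p, k), ls_a)
    bact_counts <- counts_from_proportions(split_taxa_to_otus(bact_p, k), ls_b)
    rownames(algal_counts) <- ids
    rownames(bact_counts) <- ids
    algal <- otu_table(algal_counts, algal_taxonomy(colnames(algal_p), k))
    bacterial <- otu_table(bact_counts, bacterial_taxonomy(colnames(bact_p), k))
    sites <- data.frame(sample_id = ids, location = locs, geochem, field,
                        stringsAsFactors = FALSE)
    structure(list(algal = algal, bacterial = bacterial, sites = sites,
                   config = config, seed = seed),
              class = "snow_study")
  })
}

#' @export
print.snow_study <- function(x, ...) {
  cat(sprintf("Synthetic red-snow study: %d sites (%s), seed %d\n",
              nrow(x$sites),
              paste(sprintf("%s=%d", names(x$config$locations),
                            x$config$locations), collapse = ", "),
              x$seed))
  invisible(x)
}
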