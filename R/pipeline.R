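#' Between/within location separation on ordination scores
#'
#' A scalar summary of how strongly samples cluster by location in an
#' ordination: the mean distance of each sample's location centroid from
#' the grand centroid, divided by the mean distance of each sample from its
#' own location centroid. Larger values mean cleaner geographic clustering.
#'
#' @param scores samples x components score matrix (the first `k` columns
#'   are used).
#' @param groups location labels per sample.
#' @param k number of leading components (default 2, the plotted plane).
#' @return Non-negative separation ratio.
#' @export
location_separation <- function(scores, groups, k = 2L) {
  k <- min(k, ncol(scores))
  s <- scores[, seq_len(k), drop = FALSE]
  groups <- factor(groups)
  grand <- colMeans(s)
  cents <- apply(s, 2, function(col) tapply(col, groups, mean))
  cents <- matrix(cents, nrow = nlevels(groups),
                  dimnames = list(levels(groups), colnames(s)))
  between <- sqrt(rowSums(sweep(cents, 2, grand)^2))[as.character(groups)]
  within <- sqrt(rowSums((s - cents[as.character(groups), , drop = FALSE])^2))
  mean(between) / mean(within)
}

#' Run the full community + field analysis on a study
#'
#' Chains the community statistics (singleton exclusion, rarefaction to the
#' minimum library size, rank aggregation — class for bacteria, species for
#' algae — relative abundance, Shannon diversity, PCA ordination, per-taxon
#' location ANOVA, taxon-geochemistry correlations) and the field metrics
#' (albedo with QC, biomass, the biomass-albedo Pearson test on the two
#' densely sampled locations), and summarizes the bacterial-vs-algal
#' biogeography contrast as a pair of location-separation ratios.
#'
#' @param study a `snow_study` from [simulate_study()] or [read_study()].
#' @param shannon_base log base for the Shannon indices.
#' @param qc_threshold radiometer coefficient-of-variation threshold.
#' @param rarefy_seed seed for the rarefaction draws.
#' @param correlation_locations locations used for the biomass-albedo
#'   correlation (default the two densely sampled ones).
#' @return List of class `study_analysis` with elements `bacterial` and
#'   `algal` (each: rarefied aggregated table, `proportions`, `shannon`,
#'   `pca`, `anova`, `separation`), `geochem_correlations`, `field` (from
#'   [field_metrics()]), and `summary` (named scalars).
#' @export
analyse_study <- function(study, shannon_base = 2, qc_threshold = 0.10,
                          rarefy_seed = 1L,
                          correlation_locations = c("SVA", "TAR")) {
  groups <- study$sites$location
  geochem_names <- intersect(names(study$sites),
                             c("DOC", "TC", "leachable", "Fe", "NO3", "PO4"))
  geochem <- study$sites[, geochem_names, drop = FALSE]

  analyse_one <- function(tab, rank) {
    tab <- exclude_singletons(tab)
    tab <- rarefy(tab, seed = rarefy_seed)
    agg <- aggregate_rank(tab, rank)
    prop <- relative_abundance(agg)
    pca <- pca_ordination(prop)
    list(table = agg, proportions = prop,
         shannon = shannon_per_sample(agg, base = shannon_base),
         pca = pca,
         anova = anova_per_taxon(prop, groups),
         separation = location_separation(pca$scores, groups))
  }

  bact <- analyse_one(study$bacterial, "class")
  alg <- analyse_one(study$algal, "species")
  fld <- field_metrics(study$sites, qc_threshold = qc_threshold,
                       locations = correlation_locations)
  structure(list(
    bacterial = bact, algal = alg,
    geochem_correlations = taxon_geochem_correlations(bact$proportions, geochem),
    field = fld,
    summary = c(
      bacterial_separation = bact$separation,
      algal_separation = alg$separation,
      bacterial_frac_p_lt_05 = mean(bact$anova$p < 0.05),
      algal_frac_p_ge_05 = mean(alg$anova$p >= 0.05),
      biomass_albedo_r = fld$biomass_albedo$r,
      biomass_albedo_p = fld$biomass_albedo$p)),
    class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat("Red-snow study analysis\n")
  s <- x$summary
  cat(sprintf("  location separation: bacterial %.2f vs algal %.2f\n",
              s[["bacterial_separation"]], s[["algal_separation"]]))
  cat(sprintf("  ANOVA: %.0f%% of bacterial classes p<0.05; %.0f%% of algal species p>=0.05\n",
              100 * s[["bacterial_frac_p_lt_05"]], 100 * s[["algal_frac_p_ge_05"]]))
  cat(sprintf("  biomass-albedo: r = %.2f, P = %.3g\n",
              s[["biomass_albedo_r"]], s[["biomass_albedo_p"]]))
  invisible(x)
}

#' Location-structured bacterial classes of a configuration
#'
#' Classes whose configured mean proportion actually differs across
#' locations (the classes the biogeography power property is about).
#'
#' @param config a [study_config()].
#' @return Character vector of class names.
#' @export
structured_classes <- function(config) {
  m <- config$bacterial_means
  colnames(m)[apply(m, 2, function(col) diff(range(col)) > 1e-12)]
}

#' Biogeography power summary over replicated synthetic studies
#'
#' Simulates `n_studies` default studies and, for each, runs the per-taxon
#' location ANOVA on bacterial classes and algal species and compares the
#' two PCA location-separation ratios. Summarizes the cosmopolitan-algae
#' vs location-structured-bacteria contrast as attainable power.
#'
#' @param n_studies number of replicate studies.
#' @param config a [study_config()].
#' @param seed root seed; study `i` uses `seed + i`.
#' @return List: `bacterial_power` (fraction of structured-class tests with
#'   p < 0.05), `algal_null_rate` (fraction of algal species tests with
#'   p >= 0.05), `separation_wins` (fraction of studies where the bacterial
#'   separation ratio exceeds the algal one), `n_studies`.
#' @export
biogeography_power <- function(n_studies = 20L, config = study_config(),
                               seed = 1L) {
  structured <- structured_classes(config)
  bact_p <- c(); alg_p <- c(); wins <- logical(n_studies)
  for (i in seq_len(n_studies)) {
    st <- simulate_study(config, seed = seed + i)
    an <- analyse_study(st)
    ba <- an$bacterial$anova
    bact_p <- c(bact_p, ba$p[ba$taxon %in% structured])
    alg_p <- c(alg_p, an$algal$anova$p)
    wins[i] <- an$bacterial$separation > an$algal$separation
  }
  list(bacterial_power = mean(bact_p < 0.05),
       algal_null_rate = mean(alg_p >= 0.05),
       separation_wins = mean(wins),
       n_studies = n_studies)
}

#' Recovered biomass-albedo correlation over replicated studies
#'
#' For each seed, generates field measurements at the densely sampled
#' two-location scale (n = 36 sites by default) and recovers the Pearson r
#' between biovolume and albedo computed from the radiometer readings.
#'
#' @param n_seeds number of replicate field campaigns.
#' @param config a [study_config()]; only the field model is used.
#' @param n_sites number of sites per campaign.
#' @param seed root seed; campaign `i` uses `seed + i`.
#' @return List: `r` (vector of recovered correlations), `median_r`.
#' @export
coupling_calibration <- function(n_seeds = 100L, config = study_config(),
                                 n_sites = 36L, seed = 1L) {
  cfg <- config
  cfg$locations <- c(SVA = n_sites)
  r <- vapply(seq_len(n_seeds), function(i) {
    fm <- generate_field_measurements(cfg, seed = seed + i)
    alb <- vapply(seq_len(nrow(fm)), function(j)
      compute_albedo(as.numeric(fm[j, paste0("incident_", 1:5)]),
                     as.numeric(fm[j, paste0("reflected_", 1:5)]))$albedo,
      numeric(1))
    pearson_test(fm$biomass, alb)$r
  }, numeric(1))
  list(r = r, median_r = stats::median(r))
}
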