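test_that("anchor table validation enforces band and state ordering", {
  tab <- table1()
  expect_s3_class(tab, "albedo_anchor_table")
  expect_equal(tab$state, c("dry_clean", "wet_clean", "red"))
  # minimum-decrease band must not fall below the average band
  expect_error(albedo_anchor_table(average = c(0.90, 0.75, 0.65),
                                   minimum = c(0.85, 0.80, 0.77),
                                   maximum = c(0.85, 0.70, 0.53)),
               "minimum >= average")
  # red snow cannot be brighter than wet clean snow in any band
  expect_error(albedo_anchor_table(average = c(0.90, 0.65, 0.75),
                                   minimum = c(0.95, 0.70, 0.80),
                                   maximum = c(0.85, 0.53, 0.70)),
               "dry_clean >= wet_clean >= red")
  expect_error(albedo_anchor_table(average = c(1.2, 0.75, 0.65),
                                   minimum = c(1.3, 0.80, 0.77),
                                   maximum = c(1.1, 0.70, 0.53)),
               "fractions")
})

test_that("scenario anchors follow the clean and red melt templates", {
  tab <- table1()
  clean <- build_scenario_anchors(tab, "clean")
  expect_equal(clean$day, c(0, 25, 50, 100))
  expect_equal(clean$albedo, c(0.90, 0.80, 0.75, 0.70))
  red <- build_scenario_anchors(tab, "red")
  expect_equal(red$albedo, c(0.90, 0.77, 0.65, 0.53))
  # a constant table yields a constant series
  flat <- albedo_anchor_table(rep(0.5, 3), rep(0.5, 3), rep(0.5, 3))
  expect_equal(build_scenario_anchors(flat, "red")$albedo, rep(0.5, 4))
})

test_that("band anchors track one column through days 0/50/100", {
  tab <- table1()
  expect_equal(build_band_anchors(tab, "minimum")$albedo, c(0.95, 0.80, 0.77))
  expect_equal(build_band_anchors(tab, "average")$albedo, c(0.90, 0.75, 0.65))
  expect_equal(build_band_anchors(tab, "maximum")$albedo, c(0.85, 0.70, 0.53))
  expect_equal(build_band_anchors(tab, "maximum")$day, c(0, 50, 100))
  expect_error(build_band_anchors(tab, "median"))
})

test_that("sqrt-decay fit matches the closed-form normal equations", {
  tab <- table1()
  for (scn in c("clean", "red")) {
    series <- build_scenario_anchors(tab, scn)
    fit <- fit_sqrt_decay(series)
    oracle <- ols_sqrt_oracle(series$day, series$albedo)
    expect_equal(fit$a, oracle$a, tolerance = 1e-12)
    expect_equal(fit$b, oracle$b, tolerance = 1e-12)
    # least-squares normal equations: residuals sum to 0, orthogonal to sqrt(t)
    expect_equal(sum(fit$residuals), 0, tolerance = 1e-12)
    expect_equal(sum(fit$residuals * sqrt(series$day)), 0, tolerance = 1e-12)
  }
  clean <- fit_sqrt_decay(build_scenario_anchors(tab, "clean"))
  red <- fit_sqrt_decay(build_scenario_anchors(tab, "red"))
  expect_equal(clean$a, 0.89924, tolerance = 1e-3)
  expect_equal(clean$b, 0.02025, tolerance = 1e-3)
  expect_equal(red$a, 0.91774, tolerance = 1e-3)
  expect_equal(red$b, 0.03720, tolerance = 1e-3)
})

test_that("two anchors are fitted exactly and degenerate abscissae fail", {
  fit <- fit_sqrt_decay(data.frame(day = c(0, 100), albedo = c(0.9, 0.7)))
  expect_equal(fit$a, 0.9)
  expect_equal(fit$b, 0.02)
  expect_equal(fit$rss, 0)
  expect_error(fit_sqrt_decay(data.frame(day = c(4, 4), albedo = c(0.9, 0.7))),
               "singular")
  expect_error(fit_sqrt_decay(data.frame(day = 0, albedo = 0.9)), "at least 2")
})

test_that("closed-form integral agrees with numeric quadrature", {
  set.seed(42)
  for (i in 1:25) {
    fit <- structure(list(a = runif(1, 0.5, 1), b = runif(1, 0, 0.05)),
                     class = "sqrt_decay_fit")
    horizon <- runif(1, 1, 200)
    quad <- stats::integrate(function(t) fit$a - fit$b * sqrt(t), 0, horizon,
                             rel.tol = 1e-12)$value
    expect_equal(integrate_albedo(fit, horizon), quad, tolerance = 1e-8)
  }
  const <- structure(list(a = 1, b = 0), class = "sqrt_decay_fit")
  expect_equal(integrate_albedo(const, 10), 10)
  expect_equal(integrate_albedo(const, 0), 0)
  expect_error(integrate_albedo(const, -1), "non-negative")
})

test_that("scenario differencing obeys both sign conventions", {
  f1 <- structure(list(a = 1, b = 0.01), class = "sqrt_decay_fit")
  f2 <- structure(list(a = 1, b = 0.02), class = "sqrt_decay_fit")
  d <- scenario_difference(f1, f2, 100, "sum")
  expect_equal(d$term_a, 0)
  expect_equal(d$term_b, 20 / 3, tolerance = 1e-12)
  expect_equal(d$combined, 20 / 3, tolerance = 1e-12)
  expect_equal(scenario_difference(f1, f2, 100, "difference")$combined, -20 / 3,
               tolerance = 1e-12)
  # self-difference vanishes for any horizon
  for (h in c(1, 50, 100)) {
    self <- scenario_difference(f1, f1, h)
    expect_equal(c(self$term_a, self$term_b, self$combined), c(0, 0, 0))
  }
})

test_that("a faster red-snow decay strictly increases the combined change", {
  clean <- fit_sqrt_decay(build_scenario_anchors(table1(), "clean"))
  bs <- seq(clean$b + 0.005, clean$b + 0.05, length.out = 6)
  combs <- vapply(bs, function(b2) {
    red <- structure(list(a = clean$a, b = b2), class = "sqrt_decay_fit")
    scenario_difference(clean, red, 100, "sum")$combined
  }, numeric(1))
  expect_true(all(diff(combs) > 0))
})

test_that("band sensitivity reproduces the printed coefficients and range", {
  sens <- sensitivity_analysis(table1(), 100)
  expect_equal(round(sens$min_vs_avg$coef_a, 4), 0.0409)
  expect_equal(round(sens$min_vs_avg$coef_b, 4), 0.0038)
  expect_equal(round(sens$avg_vs_max$combined, 2), 0.28)
  expect_equal(sens$range_magnitude, 0.3)
  # a band table symmetric about the average column gives equal comparisons
  expect_equal(sens$min_vs_avg$coef_a, sens$avg_vs_max$coef_a, tolerance = 1e-12)
  sym <- albedo_anchor_table(average = c(0.90, 0.75, 0.65),
                             minimum = c(0.92, 0.77, 0.67),
                             maximum = c(0.88, 0.73, 0.63))
  ssym <- sensitivity_analysis(sym, 100)
  expect_equal(ssym$min_vs_avg$coef_b, ssym$avg_vs_max$coef_b, tolerance = 1e-12)
})

test_that("the integrated report reproduces every printed worked-example value", {
  rep <- integrated_albedo_report(table1(), 100)
  expect_equal(rep$term_a, 1.85)
  expect_equal(round(rep$difference$term_b, 1), 11.3)
  expect_equal(rep$combined, 13.15)
  expect_equal(rep$headline_percent, 13)
  expect_equal(round(rep$sensitivity$min_vs_avg$coef_a, 4), 0.0409)
  expect_equal(round(rep$sensitivity$min_vs_avg$coef_b, 4), 0.0038)
  expect_equal(rep$sensitivity$range_magnitude, 0.3)
  flat <- albedo_anchor_table(rep(0.6, 3), rep(0.6, 3), rep(0.6, 3))
  expect_equal(integrated_albedo_report(flat, 100)$headline_percent, 0)
})

test_that("report serialization is numerically identical across formats", {
  rep <- integrated_albedo_report(table1(), 100)
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".txt")
  flat <- write_albedo_report(rep, json_path = jp, text_path = tp)
  from_json <- jsonlite::read_json(jp, simplifyVector = TRUE)
  txt <- readLines(tp)
  from_text <- as.numeric(sub(".*=", "", txt))
  names(from_text) <- sub("=.*", "", txt)
  expect_equal(unlist(flat), unlist(from_json)[names(unlist(flat))])
  expect_equal(unname(from_text), unname(unlist(flat)), tolerance = 1e-9)
})
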