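test_that("area assignment is a deterministic lookup with fallback and priority", {
  tbl <- make_regions(c(10, 20, 30),
                      province = c("Zhejiang", "Atlantis", "Guangdong"))
  a <- assign_areas(tbl)
  expect_equal(a$area, c("Yangtze River Delta", "other", "Pearl River Delta"))

  # duplicate listing resolves to the higher-priority area with a warning
  dup_map <- c(Hubei = "Yangtze River Basin", Hubei = "Bohai Rim")
  expect_warning(a2 <- assign_areas(make_regions(5, province = "Hubei"),
                                    dup_map),
                 "more than one area")
  expect_equal(a2$area, "Bohai Rim")
  expect_error(assign_areas(tbl, c(Hubei = "Mars")),
               class = "crsoil_config_error")
})

test_that("area class distributions report per-area fractions that sum to 1", {
  tbl <- make_regions(91.5 * 2^c(-1, -2, 6, 7), province = "Zhejiang")
  res <- assess_regions(tbl)
  acd <- area_class_distribution(assign_areas(tbl), res)
  ig <- acd$igeo_class_fractions
  expect_equal(ig$class0, 0.5)
  expect_equal(ig$class6, 0.5)
  expect_equal(unname(rowSums(ig[, -1])), 1)
  expect_equal(unname(rowSums(acd$e_class_fractions[, -1])), 1)

  # 8 extremely-contaminated of 103 delta regions -> 7.77%;
  # 5 significant-high-E of 103 -> 4.85%
  # 5 regions in both the top Igeo class and the top E class, 3 more only
  # in the top Igeo class (E = 2 * cn / 61 crosses 320 at cn = 9760)
  cr <- c(rep(91.5 * 2^7, 5), rep(91.5 * 2^5.5, 3), rep(200, 95))
  tbl2 <- make_regions(cr, province = "Jiangsu")
  acd2 <- area_class_distribution(assign_areas(tbl2), assess_regions(tbl2))
  expect_equal(round(100 * acd2$igeo_class_fractions$class6, 2), 7.77)
  expect_equal(round(100 * acd2$e_class_fractions$significant_high, 2), 4.85)
})

test_that("exceedance shares by area match counts and handle degenerate cases", {
  tbl <- fixture_506()
  exc <- exceedance_by_area(tbl)
  expect_equal(sum(exc$n_exceed), 21)
  yrd <- exc[exc$area == "Yangtze River Delta", ]
  expect_equal(yrd$n_exceed, 8)
  expect_equal(round(yrd$share_pct, 1), 38.1)
  expect_equal(sum(exc$share_pct), 100)

  none <- exceedance_by_area(make_regions(c(10, 20), province = "Hubei"))
  expect_equal(none$share_pct, 0)

  all_one <- exceedance_by_area(make_regions(c(9000, 8000),
                                             province = "Guangdong"))
  expect_equal(all_one$share_pct, 100)
})

test_that("yearly medians use mean-of-middle-two and ignore input order", {
  tbl <- make_regions(c(10, 1000), year = 2010)
  expect_equal(yearly_medians(tbl)$median, 505)

  set.seed(4)
  tbl2 <- make_regions(exp(rnorm(300, 5, 1)),
                       year = sample(2002:2021, 300, replace = TRUE))
  ym <- yearly_medians(tbl2)
  expect_lte(nrow(ym), 20)
  expect_identical(ym, yearly_medians(tbl2[sample(300), ]))
  expect_identical(ym$year, sort(ym$year))

  tbl3 <- make_regions(c(5, 6)); tbl3$sampling_year <- NA
  expect_warning(empty <- yearly_medians(tbl3), "no records")
  expect_equal(nrow(empty), 0)
})

test_that("trend fitting recovers exact polynomials and degenerates safely", {
  years <- 2002:2021
  med <- 10^(-0.01 * (years - 2009)^2 + 2)
  fit <- fit_trend(data.frame(year = years, median = med))
  expect_equal(fit$vertex_year, 2009, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # de-centered calendar-year coefficients reproduced
  expect_equal(unname(fit$coefficients),
               c(-0.01 * 2009^2 + 2, 2 * 0.01 * 2009, -0.01),
               tolerance = 1e-9)
  expect_equal(unname(coef(fit)), unname(fit$coefficients))
  expect_equal(unname(predict(fit, 2009)), 100)  # peak median, mg/kg

  # linear truth: curvature below tolerance, vertex reported absent
  lin <- fit_trend(data.frame(year = years, median = 10^(0.02 * (years - 2000))))
  expect_true(is.na(lin$vertex_year))

  expect_error(fit_trend(data.frame(year = 2002:2003, median = c(1, 2))),
               class = "crsoil_input_error")

  # natural-log and cubic variants are consistent with the quadratic fit
  fit_ln <- fit_trend(data.frame(year = years, median = med), log_base = "ln")
  expect_equal(fit_ln$vertex_year, 2009, tolerance = 1e-9)
  fit3 <- fit_trend(data.frame(year = years, median = med), degree = 3)
  expect_equal(unname(fit3$coefficients[4]), 0, tolerance = 1e-9)
})

test_that("vertex recovery on paper-like synthetic data stays within a year and a half", {
  errs <- vapply(1:10, function(s) {
    r <- generate_regions(default_paperlike_spec(seed = 300 + s,
                                                 n_regions = 2000))
    fit_trend(yearly_medians(r))$vertex_year - 2009
  }, numeric(1))
  expect_true(all(abs(errs) <= 1.5))
})
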