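# Reference profile used by the hand-arithmetic oracles below.
oracle_profile <- function() {
  receptor_profile("child", IngR = 100, InhR = 7.6, SA = 2800, AF = 0.2,
                   ABS = 0.001, EF = 350, ED = 6, BW = 15, AT = 2190)
}

test_that("pathway doses match hand-computed oracles and scale linearly", {
  p <- oracle_profile()
  expect_equal(signif(add_ingestion(100, p), 4), 6.393e-4)
  expect_equal(signif(add_dermal(100, p), 4), 3.580e-6)
  # 100 * 7.6 * 350 * 6 / (1.36e9 * 15 * 2190) = 1.596e6 / 4.4676e13
  expect_equal(signif(add_inhalation(100, p), 4), 3.572e-8)

  # linearity in cn, down to the zero limit
  expect_equal(add_ingestion(0, p), 0)
  expect_equal(add_ingestion(200, p), 2 * add_ingestion(100, p))
  expect_equal(add_dermal(50, p), 0.5 * add_dermal(100, p))

  # dermal dose linear in adherence; inhalation inverse in PEF
  p2 <- oracle_profile(); p2$AF <- 2 * p$AF
  expect_equal(add_dermal(100, p2), 2 * add_dermal(100, p))
  p3 <- oracle_profile(); p3$PEF <- 10 * p$PEF
  expect_equal(add_inhalation(100, p3), add_inhalation(100, p) / 10)

  expect_error(receptor_profile("child", IngR = 100, InhR = 7.6, SA = 2800,
                                AF = 0.2, ABS = 0, EF = 350, ED = 6,
                                BW = 15, AT = 2190),
               class = "crsoil_domain_error")  # ABS = 0 not allowed
  expect_error(add_ingestion(-1, p), class = "crsoil_domain_error")
})

test_that("hazard quotients divide doses by reference doses and sum", {
  p <- oracle_profile()
  # reference doses equal to the doses themselves force HQ = 1 per pathway
  tox <- toxicity_params(rfd_ing = add_ingestion(100, p),
                         rfd_derm = add_dermal(100, p),
                         rfd_inh = add_inhalation(100, p))
  hq <- hazard_quotients(100, p, tox)
  expect_equal(hq$hq_total, 3)
  expect_true(hq$exceeds_1)

  hq2 <- hazard_quotients(c(10, 100), p, toxicity_params(), region_id = c("a", "b"))
  expect_identical(hq2$hq_total, hq2$hq_ing + hq2$hq_derm + hq2$hq_inh)
  expect_identical(hq2$exceeds_1, hq2$hq_total > 1)

  # restricting pathways restricts the total
  hq3 <- hazard_quotients(100, p, toxicity_params(), pathways = "ing")
  expect_equal(hq3$hq_total, hq3$hq_ing)
})

test_that("hazard quotients agree with an independent single-expression oracle", {
  set.seed(99)
  for (i in 1:1000) {
    v <- runif(11, 0.01, 10)
    p <- receptor_profile("adult_male", IngR = v[1] * 100, InhR = v[2] * 10,
                          SA = v[3] * 1000, AF = v[4], ABS = min(v[5] / 10, 1),
                          EF = v[6] * 36, ED = v[7] * 5, BW = v[8] * 20,
                          AT = v[9] * 1000, PEF = v[10] * 1e9)
    tox <- toxicity_params(rfd_ing = v[11] * 1e-3, rfd_derm = v[11] * 1e-4,
                           rfd_inh = v[11] * 1e-5)
    cn <- v[1] * 500
    got <- hazard_quotients(cn, p, tox)$hq_total
    want <- cn * p$EF * p$ED / (p$BW * p$AT) *
      (p$IngR * p$CF / tox$rfd_ing +
         p$SA * p$AF * p$ABS * p$CF / tox$rfd_derm +
         p$InhR / (p$PEF * tox$rfd_inh))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("receptor comparisons are concentration-independent and children dominate", {
  rec <- default_receptors()
  tox <- toxicity_params()
  hq_at <- function(cn, p) hazard_quotients(cn, p, tox)$hq_total
  r1 <- hq_at(50, rec$child) / hq_at(50, rec$adult_male)
  r2 <- hq_at(5000, rec$child) / hq_at(5000, rec$adult_male)
  expect_equal(r1, r2)
  # with the shipped defaults children carry the highest risk at equal cn
  expect_gt(hq_at(100, rec$child), hq_at(100, rec$adult_male))
  expect_gt(hq_at(100, rec$child), hq_at(100, rec$adult_female))
})

test_that("HQ summaries report means, exceedance shares and national ratios", {
  tbl <- make_regions(c(100, 200), type = "M")
  res <- data.frame(region_id = tbl$region_id, group = "child",
                    hq_total = c(0.5, 1.5), stringsAsFactors = FALSE)
  s <- suppressWarnings(summarize_hq(res, tbl))
  expect_equal(s$by_group$mean_hq, 1)
  expect_equal(s$by_group$pct_above_1, 50)

  # ratios to the national mean computed from unrounded means
  n_c <- 26; n_t <- 17; n_rest <- 506 - n_c - n_t
  rest_val <- (506 * 4.28e-2 - n_c * 3.82e-1 - n_t * 4.73e-1) / n_rest
  tbl2 <- make_regions(rep(100, 506),
                       type = rep(c("C", "T", "M"), c(n_c, n_t, n_rest)))
  res2 <- data.frame(region_id = tbl2$region_id, group = "child",
                     hq_total = rep(c(3.82e-1, 4.73e-1, rest_val),
                                    c(n_c, n_t, n_rest)),
                     stringsAsFactors = FALSE)
  s2 <- suppressWarnings(summarize_hq(res2, tbl2))
  ratio <- function(ty) s2$by_type$ratio_to_national[
    s2$by_type$industry_type == ty]
  expect_equal(round(ratio("T"), 2), 11.05)
  expect_equal(round(ratio("C"), 2), 8.93)
  expect_error(summarize_hq(res[0, ]), class = "crsoil_input_error")
})
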