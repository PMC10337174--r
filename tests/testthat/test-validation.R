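test_that("Wilson intervals hit their closed form and boundary behaviour", {
  expect_equal(proportion_ci(0, 10)$low, 0)
  expect_equal(proportion_ci(10, 10)$high, 1)
  expect_error(proportion_ci(0, 0), class = "ipfvalid_value_error")

  # independent closed-form score-interval computation
  wilson_oracle <- function(x, n, level = 0.95) {
    z <- qnorm(1 - (1 - level) / 2)
    p <- x / n
    c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n),
      (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n))
  }
  cases <- list(c(6113, 9498), c(1, 2), c(974, 1190), c(50, 10000), c(3, 3))
  for (cs in cases) {
    got <- proportion_ci(cs[1], cs[2])
    want <- wilson_oracle(cs[1], cs[2])
    expect_equal(got$low, max(0, want[1]), tolerance = 1e-10)
    expect_equal(got$high, min(1, want[2]), tolerance = 1e-10)
  }
})

test_that("perfect recording gives PPV and sensitivity of one", {
  n <- 20
  reg <- make_registry(sprintf("q%02d", 1:n))
  ev <- make_events(reg$patient_id, "2010-06-01", "IPF-IPF")
  de <- purrr::map_dfr(reg$patient_id,
                       ~ make_deaths(.x, "2015-06-30", "J841"))
  co <- linked_cohort(reg, events = ev, deaths = de)
  v <- validate_algorithms(co, ipf_algorithms(c("DA1", "DA3")))
  expect_equal(v$ppv, c(1, 1))
  expect_equal(v$sensitivity, c(1, 1))
  expect_equal(v$n_gold, c(n, n))
  expect_true(all(v$ppv_low <= v$ppv & v$ppv <= v$ppv_high))

  # an algorithm that finds nobody yields an NA PPV, not an error
  v5 <- validate_algorithms(co, ipf_algorithms("DA5"))
  expect_equal(v5$n_found, 0)
  expect_true(is.na(v5$ppv))
  expect_equal(v5$sensitivity, 0)
})

test_that("concordance partitions conserve counts and recover marginals", {
  p <- concordance(c("a", "b"), c("c", "d", "e"), c("f", "g", "h", "i"))
  expect_equal(sum(p$n), 9)
  expect_equal(tidy(p)$n[tidy(p)$region == "all_three"], 0)

  p <- concordance(letters[1:5], letters[1:5], letters[1:5])
  expect_equal(attr(p, "total"), 5)
  expect_equal(p$n[p$region == "all_three"], 5)
  expect_equal(sum(p$n[p$region != "all_three"]), 0)

  set.seed(13)
  for (i in 1:50) {
    pool <- sprintf("x%03d", 1:80)
    a <- sample(pool, sample(0:60, 1))
    h <- sample(pool, sample(0:60, 1))
    o <- sample(pool, sample(0:60, 1))
    p <- concordance(a, h, o)
    expect_equal(sum(p$n), length(unique(c(a, h, o))))
    m <- attr(p, "marginals")
    expect_equal(m[["aurum"]], length(unique(a)))
    expect_equal(m[["hes"]], length(unique(h)))
    expect_equal(m[["ons"]], length(unique(o)))
  }
})

test_that("inclusion-exclusion recovers the unprinted pairwise overlap", {
  # oracle: |A intersect H| from the inclusion-exclusion identity, longhand
  ie_oracle <- function(total, a, h, o, ao, ho, aho) a + h + o - ao - ho + aho - total
  p <- derive_pairwise_from_marginals(17559, 9498, 10714, 11295,
                                      6113, 6651, 4304, 8460)
  ah <- p$n[p$region == "aurum_hes"] + p$n[p$region == "all_three"]
  expect_equal(ah, ie_oracle(17559, 9498, 10714, 11295, 6113, 6651, 4304))
  expect_equal(ah, 5488)
  expect_equal(attr(p, "total"), 17559)
  expect_equal(unname(attr(p, "marginals")), c(9498, 10714, 11295))

  expect_error(derive_pairwise_from_marginals(100, 10, 20, 30, 15, 5, 2),
               "infeasible", class = "ipfvalid_infeasible_error")
  z <- derive_pairwise_from_marginals(0, 0, 0, 0, 0, 0, 0)
  expect_true(all(z$n == 0))
  expect_error(derive_pairwise_from_marginals(17559, 9498, 10714, 11295,
                                              6113, 6651, 4304, 9999),
               "inconsistent", class = "ipfvalid_infeasible_error")
})

test_that("gold restriction to underlying cause never enlarges any overlap", {
  co <- generate_cohort(generator_config(n_patients = 3000, seed = 17))
  sg <- sensitivity_analysis_gold(co)
  s <- sg$summary
  expect_lte(s$n_ons[2], s$n_ons[1])
  expect_lte(s$aurum_ons[2], s$aurum_ons[1])
  expect_lte(s$hes_ons[2], s$hes_ons[1])
  expect_lte(s$all_three[2], s$all_three[1])

  # when every certificate IPF code is the underlying cause, the two
  # partitions coincide
  cfg <- generator_config(n_patients = 800, seed = 23,
                          p_underlying_given_cert = 1)
  co2 <- generate_cohort(cfg)
  sg2 <- sensitivity_analysis_gold(co2)
  expect_equal(tidy(sg2$anywhere)$n, tidy(sg2$underlying_only)$n)
})

test_that("relaxing the position rule grows the hospital cohort monotonically", {
  co <- generate_cohort(generator_config(n_patients = 3000, seed = 29))
  sp <- sensitivity_analysis_positions(co)
  expect_gte(sp$n_hes[2], sp$n_hes[1])
  expect_gte(sp$n_hes_ons[2], sp$n_hes_ons[1])

  # with no position-3-only admissions the two rules agree
  co2 <- generate_cohort(generator_config(n_patients = 800, seed = 31,
                                          p_position3_only = 0))
  sp2 <- sensitivity_analysis_positions(co2)
  expect_equal(sp2$n_hes[1], sp2$n_hes[2])
  expect_equal(sp2$n_hes_ons[1], sp2$n_hes_ons[2])
})

test_that("validation results stay within probability bounds on random data", {
  co <- generate_cohort(generator_config(n_patients = 2000, seed = 37))
  v <- validate_algorithms(co)
  expect_true(all(v$n_true <= pmin(v$n_found, v$n_gold)))
  ok <- !is.na(v$ppv)
  expect_true(all(v$ppv[ok] >= 0 & v$ppv[ok] <= 1))
  expect_true(all(v$sensitivity >= 0 & v$sensitivity <= 1))
  expect_true(all(v$ppv_low[ok] <= v$ppv[ok] & v$ppv[ok] <= v$ppv_high[ok]))

  # switching the gold standard to underlying-only can only shrink the
  # confirmed counts and the shared denominator
  vu <- validate_algorithms(co, gold = "underlying_only")
  expect_true(all(vu$n_true <= v$n_true))
  expect_true(all(vu$n_gold <= v$n_gold))
})
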