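test_that("earliest code match is the filter-then-min of the event stream", {
  ev <- make_events("p1", c("2012-05-10", "2011-03-02", "2013-01-01"),
                    c("PF-PULMFIB", "IPF-IPF", "ZZZ"))
  broad <- codelist_codes(default_ipf_codelist(), "broad")
  got <- earliest_code_match(ev, broad)
  expect_equal(got$first_date, as.Date("2011-03-02"))
  expect_equal(nrow(earliest_code_match(make_events("p1", "2011-01-01", "ZZZ"),
                                        broad)), 0)

  # 500 random event streams against the brute-force oracle
  set.seed(21)
  codes <- c("IPF-IPF", "PF-PULMFIB", "PF-FIBALV", "XX1", "XX2")
  for (i in 1:500) {
    n <- sample(0:6, 1)
    if (n == 0) next
    ev <- make_events("p", as.Date("2010-01-01") + sample(0:3000, n, TRUE),
                      sample(codes, n, TRUE))
    keep <- ev$event_date[ev$code %in% broad]
    want <- if (length(keep)) min(keep) else NULL
    got <- earliest_code_match(ev, broad)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$first_date, want)
    }
  }
})

test_that("qualifying admissions respect diagnosis position rules", {
  sp <- make_spell("p1", "2012-06-01", c("I500", "J84.1"))
  got <- qualifying_admissions(sp, rule = "primary_or_secondary")
  expect_equal(got$admission_date, as.Date("2012-06-01"))

  # the IPF code only in position 3: excluded under primary/secondary,
  # captured under the top-3 rule
  sp3 <- make_spell("p1", "2012-06-01", c("I500", "J189", "J841"))
  expect_equal(nrow(qualifying_admissions(sp3, rule = "primary_or_secondary")), 0)
  expect_equal(qualifying_admissions(sp3, rule = "top3")$admission_date,
               as.Date("2012-06-01"))

  empty <- sp[0, ]
  expect_equal(nrow(qualifying_admissions(empty)), 0)

  # earliest of several qualifying admissions wins; window restriction bites
  sp2 <- dplyr::bind_rows(make_spell("p1", "2014-01-01", c("J841", "I509")),
                          make_spell("p1", "2012-06-01", c("J848", "I509")))
  expect_equal(qualifying_admissions(sp2)$admission_date, as.Date("2012-06-01"))
  win <- tibble::tibble(patient_id = "p1", fu_start = as.Date("2013-01-01"),
                        fu_end = as.Date("2015-01-01"))
  expect_equal(qualifying_admissions(sp2, window = win)$admission_date,
               as.Date("2014-01-01"))
})

test_that("death-certificate matching distinguishes anywhere from underlying", {
  d1 <- make_deaths("p1", "2015-01-01", "J841")
  expect_true(death_has_ipf(d1, mode = "anywhere")$ipf_death)
  expect_true(death_has_ipf(d1, mode = "underlying_only")$ipf_death)

  d2 <- make_deaths("p2", "2015-01-01", "I219", "J849")
  expect_true(death_has_ipf(d2, mode = "anywhere")$ipf_death)
  expect_false(death_has_ipf(d2, mode = "underlying_only")$ipf_death)

  d3 <- make_deaths("p3", "2015-01-01", "I219", c("J189", "C349"))
  expect_false(death_has_ipf(d3, mode = "anywhere")$ipf_death)
  expect_false(death_has_ipf(d3, mode = "underlying_only")$ipf_death)
})

test_that("thoracic CT evidence ignores dates and non-CT modalities", {
  # CT after death still counts ("at any time")
  post_mortem <- make_imaging("p1", "2030-01-01")
  expect_true(has_hrct_evidence(post_mortem)$hrct)
  xray <- make_imaging("p1", "2012-01-01", modality = "XRAY")
  expect_false(has_hrct_evidence(xray)$hrct)
  ct_abdo <- make_imaging("p1", "2012-01-01", body_region = "other")
  expect_false(has_hrct_evidence(ct_abdo)$hrct)
  expect_equal(nrow(has_hrct_evidence(xray[0, ])), 0)
})

test_that("other-ILD exclusion matches anywhere in the record", {
  excl <- default_ild_codelist()
  hit <- make_events("p1", "2005-01-01", "ILD-CTD")
  expect_true(has_other_ild_cause(hit, excl)$other_ild)
  expect_equal(nrow(has_other_ild_cause(hit[0, ], excl)), 0)

  set.seed(31)
  codes <- c("ILD-CTD", "ILD-SARC", "AAA", "BBB")
  for (i in 1:100) {
    n <- sample(1:5, 1)
    ev <- make_events("p", as.Date("2010-01-01") + sample(0:999, n, TRUE),
                      sample(codes, n, TRUE))
    want <- any(ev$code %in% codelist_codes(excl))
    expect_equal(has_other_ild_cause(ev, excl)$other_ild, want)
  }
})

test_that("algorithms conjoin their criteria over a patient's linked record", {
  broad_only <- one_patient_cohort(
    events = make_events("p1", "2010-06-01", "PF-PULMFIB"))
  f <- patient_features(broad_only)
  expect_true(apply_algorithm(f, ipf_algorithms("DA1")))
  expect_false(apply_algorithm(f, ipf_algorithms("DA7")))  # no admission
  expect_false(apply_algorithm(f, ipf_algorithms("DA3")))  # broad, not narrow

  narrow_hosp <- one_patient_cohort(
    events = make_events("p1", "2010-06-01", "IPF-IPF"),
    spells = make_spell("p1", "2012-06-01", c("J841", "I509")))
  f <- patient_features(narrow_hosp)
  expect_true(apply_algorithm(f, ipf_algorithms("DA8")))
  expect_true(apply_algorithm(f, ipf_algorithms("DA7")))
  expect_true(apply_algorithm(f, ipf_algorithms("DA5")))

  # an exclusion code defeats DA2 even with CT evidence
  excluded <- one_patient_cohort(
    events = make_events("p1", c("2010-06-01", "2009-01-01"),
                         c("PF-PULMFIB", "ILD-SARC")),
    imaging = make_imaging("p1", "2011-01-01"))
  f <- patient_features(excluded)
  expect_false(apply_algorithm(f, ipf_algorithms("DA2")))
  not_excluded <- one_patient_cohort(
    events = make_events("p1", "2010-06-01", "PF-PULMFIB"),
    imaging = make_imaging("p1", "2011-01-01"))
  expect_true(apply_algorithm(patient_features(not_excluded),
                              ipf_algorithms("DA2")))

  expect_error(ipf_algorithms("DA9"), "unknown algorithm",
               class = "ipfvalid_config_error")
  expect_error(algorithm("bad", "none"), class = "ipfvalid_config_error")
})

test_that("algorithm counts are monotone in their conjuncts on generated data", {
  co <- generate_cohort(generator_config(n_patients = 4000, seed = 99))
  f <- patient_features(co)
  counts <- vapply(seq_len(8), function(i) {
    sum(apply_algorithm(f, ipf_algorithms()[i, ]) & f$deceased & f$eligible)
  }, numeric(1))
  names(counts) <- paste0("DA", 1:8)
  expect_lte(counts[["DA3"]], counts[["DA1"]])
  expect_lte(counts[["DA4"]], counts[["DA2"]])
  expect_lte(counts[["DA2"]], counts[["DA1"]])
  expect_lte(counts[["DA8"]], counts[["DA7"]])
  expect_lte(counts[["DA7"]], counts[["DA1"]])
  expect_lte(counts[["DA6"]], counts[["DA5"]])
  expect_lte(counts[["DA7"]], counts[["DA5"]])

  # relaxing the position rule never removes a qualifying patient
  ps <- qualifying_admissions(co$spells, rule = "primary_or_secondary")
  t3 <- qualifying_admissions(co$spells, rule = "top3")
  anyp <- qualifying_admissions(co$spells, rule = "any_position")
  expect_true(all(ps$patient_id %in% t3$patient_id))
  expect_true(all(t3$patient_id %in% anyp$patient_id))

  # purity: permuting patients leaves per-patient results unchanged
  set.seed(5)
  perm <- sample(nrow(f))
  da2 <- ipf_algorithms("DA2")
  expect_identical(apply_algorithm(f[perm, ], da2),
                   apply_algorithm(f, da2)[perm])
  expect_identical(apply_algorithm(f, da2), apply_algorithm(f, da2))
})
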