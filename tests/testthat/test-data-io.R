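test_that("registry files round-trip through read and write in file order", {
  path <- file.path(mini_cohort_dir(), "registry.csv")
  reg <- read_ehr_table(path, "registry")
  expect_equal(nrow(reg), 5)
  expect_equal(reg$patient_id, sprintf("p%02d", 1:5))
  expect_s3_class(reg$birth_date, "Date")
  expect_true(is.na(reg$death_date[4]))

  out <- withr::local_tempfile(fileext = ".csv")
  write_ehr_table(reg, out)
  expect_identical(readLines(out), readLines(path))
  expect_equal(read_ehr_table(out, "registry"), reg)
})

test_that("tab-delimited input is sniffed from the header line", {
  out <- withr::local_tempfile(fileext = ".tsv")
  reg <- read_ehr_table(file.path(mini_cohort_dir(), "registry.csv"), "registry")
  write_ehr_table(reg, out, delim = "\t")
  expect_equal(read_ehr_table(out, "registry"), reg)
})

test_that("schema and parse errors name the offending column and row", {
  out <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,event_date,code", "p1,2010-01-01,X"), out)
  expect_error(read_ehr_table(out, "events"), "term",
               class = "ipfvalid_schema_error")

  writeLines(c("patient_id,event_date,code,term",
               "p1,2010-01-01,X,t", "p2,2010-13-40,Y,t"), out)
  expect_error(read_ehr_table(out, "events"), "row 2",
               class = "ipfvalid_parse_error")
})

test_that("registry integrity invariants are enforced", {
  dup <- dplyr::bind_rows(make_registry("p1"), make_registry("p1"))
  expect_error(validate_ehr_table(dup, "registry"), "duplicate patient_id",
               class = "ipfvalid_integrity_error")

  bad <- make_registry("p1", birth_date = "1990-01-01", death_date = "1985-01-01")
  expect_error(validate_ehr_table(bad, "registry"), "birth_date not before",
               class = "ipfvalid_integrity_error")

  bad <- make_registry("p1", registration_start = "2010-01-01",
                       transfer_out_date = "2005-01-01", death_date = NA)
  expect_error(validate_ehr_table(bad, "registry"),
               "registration_start after transfer_out_date",
               class = "ipfvalid_integrity_error")
})

test_that("episode positions must be gap-free from 1, as a brute check agrees", {
  # independent oracle: an episode is valid iff its sorted positions are 1..k
  episode_ok <- function(positions) identical(sort(positions), seq_along(positions))

  good <- make_spell("p1", "2012-01-01", c("J841", "I509"))
  expect_silent(validate_ehr_table(good, "spells"))
  expect_true(episode_ok(good$position))

  gapped <- good
  gapped$position <- c(1L, 3L)
  expect_false(episode_ok(gapped$position))
  expect_error(validate_ehr_table(gapped, "spells"), "gap in diagnosis positions",
               class = "ipfvalid_integrity_error")

  dup_pos <- good
  dup_pos$position <- c(1L, 1L)
  expect_false(episode_ok(dup_pos$position))
  expect_error(validate_ehr_table(dup_pos, "spells"), "gap in diagnosis positions",
               class = "ipfvalid_integrity_error")

  swapped <- good[2:1, ]  # order within the file must not matter
  expect_silent(validate_ehr_table(swapped, "spells"))
})

test_that("death records need exactly one underlying cause and one date", {
  ok <- make_deaths("p1", "2015-01-01", "J841", c("I509", "J189"))
  expect_silent(validate_ehr_table(ok, "deaths"))

  two_underlying <- dplyr::bind_rows(make_deaths("p1", "2015-01-01", "J841"),
                                     make_deaths("p1", "2015-01-01", "I219"))
  expect_error(validate_ehr_table(two_underlying, "deaths"),
               "exactly one underlying cause",
               class = "ipfvalid_integrity_error")

  clash <- make_deaths("p1", "2015-01-01", "J841", "I509")
  clash$death_date[2] <- as.Date("2015-01-02")
  expect_error(validate_ehr_table(clash, "deaths"), "conflicting death_date",
               class = "ipfvalid_integrity_error")
})

test_that("rated codelists parse with case-folded ratings and derived subsets", {
  cl <- read_codelist(system.file("extdata", "ipf_codelist_synthetic.tsv",
                                  package = "ipfvalid"))
  expect_s3_class(cl, "ipf_codelist")
  expect_equal(length(codelist_codes(cl, "narrow")), 3)
  expect_equal(length(codelist_codes(cl, "broad")), 7)
  expect_true(all(codelist_codes(cl, "narrow") %in% codelist_codes(cl, "broad")))
  expect_false("PF-RADIATION" %in% codelist_codes(cl, "broad"))

  # 4 entries rated yes/maybe/maybe/no -> narrow 1, broad 3
  cl4 <- codelist(c("a", "b", "c", "d"), rating = c("yes", "maybe", "maybe", "no"))
  expect_equal(codelist_codes(cl4, "narrow"), "a")
  expect_equal(codelist_codes(cl4, "broad"), c("a", "b", "c"))

  # all rated no -> both subsets empty
  cl0 <- codelist(c("a", "b"), rating = "no")
  expect_equal(codelist_codes(cl0, "broad"), character())
  expect_equal(codelist_codes(cl0, "narrow"), character())

  # case variants are folded before validation
  out <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("code\tterm\tsystem\trating", "a\tx\tSNOMED_LIKE\tYes"), out)
  expect_equal(codelist_codes(read_codelist(out), "narrow"), "a")

  writeLines(c("code\tterm\tsystem\trating", "a\tx\tSNOMED_LIKE\tperhaps"), out)
  expect_error(read_codelist(out), "unknown rating",
               class = "ipfvalid_parse_error")
  expect_error(codelist(c("a", "a")), "duplicate code",
               class = "ipfvalid_integrity_error")
})

test_that("ICD-10 normalisation strips dots and case and is idempotent", {
  expect_equal(normalize_icd10("J84.1"), "J841")
  expect_equal(normalize_icd10(" j849 "), "J849")
  expect_equal(normalize_icd10("J84.1X"), "J841X")
  expect_error(normalize_icd10(""), class = "ipfvalid_value_error")
  expect_error(normalize_icd10(c("J841", "  ")), class = "ipfvalid_value_error")

  codes <- c("J84.1", "i50.0", " C34.9 ", "A41")
  expect_identical(normalize_icd10(normalize_icd10(codes)),
                   normalize_icd10(codes))
})

test_that("ICD-10 matching uses prefix semantics and is monotone in targets", {
  t3 <- ipf_icd10_targets()
  expect_true(icd10_matches("J84.1", t3))
  expect_false(icd10_matches("J840", t3))
  expect_true(icd10_matches("J8410", t3))
  expect_false(icd10_matches("J8410", t3, exact = TRUE))
  expect_true(icd10_matches("J841", t3, exact = TRUE))

  # brute-force prefix oracle over random codes and random target sets
  prefix_oracle <- function(code, targets) {
    norm <- normalize_icd10(code)
    any(vapply(targets, function(t) {
      nchar(norm) >= nchar(t) && substr(norm, 1, nchar(t)) == t
    }, logical(1)))
  }
  set.seed(11)
  alphabet <- c("J840", "J841", "J848", "J849", "J8410", "J84", "I509", "J96")
  for (i in 1:200) {
    code <- sample(alphabet, 1)
    targets <- sample(alphabet, sample(1:4, 1))
    expect_equal(icd10_matches(code, targets), prefix_oracle(code, targets),
                 info = paste(code, "vs", paste(targets, collapse = ",")))
    # enlarging the target set can never flip a match to a non-match
    bigger <- union(targets, sample(alphabet, 2))
    if (icd10_matches(code, targets)) expect_true(icd10_matches(code, bigger))
  }
})

test_that("cohort directories round-trip and cross-table checks fire", {
  co <- read_cohort(mini_cohort_dir())
  expect_s3_class(co, "linked_cohort")
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_equal(read_cohort(dir)$registry, co$registry)
  expect_equal(read_cohort(dir)$spells, co$spells)

  stray <- make_events("ghost", "2010-01-01", "X")
  expect_error(linked_cohort(make_registry("p1"), events = stray),
               "not present in registry", class = "ipfvalid_integrity_error")

  wrong_date <- make_deaths("p1", "2014-01-01", "J841")
  expect_error(linked_cohort(make_registry("p1", death_date = "2015-06-30"),
                             deaths = wrong_date),
               "disagrees with registry", class = "ipfvalid_integrity_error")
})
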