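#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes (vectorised).
#' @param n Number of trials, `n >= 1`.
#' @param level Confidence level, default 0.95.
#' @return A tibble with columns `low`, `high`, clipped to \[0, 1\].
#' @examples
#' proportion_ci(6113, 9498)
#' @export
proportion_ci <- function(x, n, level = 0.95) {
  if (any(n < 1)) {
    abort("proportion_ci is undefined for n = 0", class = "ipfvalid_value_error")
  }
  stopifnot(all(x >= 0), all(x <= n), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- n + z^2
  centre <- (x + z^2 / 2) / denom
  half <- z * sqrt(p * (1 - p) * n + z^2 / 4) / denom
  tibble(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Round half away from zero
#'
#' Plain decimal rounding in which .5 always rounds away from zero (the
#' convention used for the one-decimal percentages in the reports), unlike
#' base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Validate diagnostic algorithms against the death-certificate gold standard
#'
#' Because the reference standard is a death record, validation is limited
#' to study-eligible patients who died. For each algorithm, `n_found` is the
#' number of deceased patients the algorithm flags, `n_true` the subset with
#' IPF on the death certificate under `gold`, and `n_gold` all deceased
#' patients with IPF on the certificate (one shared denominator across
#' algorithms). PPV = n_true / n_found, sensitivity = n_true / n_gold, both
#' with Wilson score intervals. An algorithm that finds nobody yields an
#' `NA` PPV, not an error.
#'
#' @param cohort A [linked_cohort()], or `NULL` if `features` is given.
#' @param algorithms Algorithm definitions, default [ipf_algorithms()].
#' @param gold `"anywhere"` or `"underlying_only"`.
#' @param config A [study_config()].
#' @param level Confidence level for the intervals.
#' @param features Optional precomputed [patient_features()] (saves
#'   recomputation when validating many algorithm sets).
#' @param ... Passed to [patient_features()] when `features` is `NULL`.
#' @return A tibble of class `ipf_validation`, one row per algorithm, with
#'   counts, proportions and interval bounds.
#' @export
validate_algorithms <- function(cohort, algorithms = ipf_algorithms(),
                                gold = c("anywhere", "underlying_only"),
                                config = study_config(), level = 0.95,
                                features = NULL, ...) {
  gold <- match.arg(gold)
  if (is.null(features)) features <- patient_features(cohort, config = config, ...)
  pool <- features |> filter(.data$eligible, .data$deceased)
  gold_flag <- if (gold == "anywhere") pool$ipf_death_any else pool$ipf_death_underlying
  n_gold <- sum(gold_flag)
  rows <- purrr::map_dfr(seq_len(nrow(algorithms)), function(i) {
    da <- algorithms[i, ]
    found <- apply_algorithm(pool, da)
    n_found <- sum(found)
    n_true <- sum(found & gold_flag)
    ppv <- if (n_found > 0) n_true / n_found else NA_real_
    ppv_ci <- if (n_found > 0) proportion_ci(n_true, n_found, level) else
      tibble(low = NA_real_, high = NA_real_)
    sens <- if (n_gold > 0) n_true / n_gold else NA_real_
    sens_ci <- if (n_gold > 0) proportion_ci(n_true, n_gold, level) else
      tibble(low = NA_real_, high = NA_real_)
    tibble(algorithm_id = da$id, description = da$description,
           n_found = n_found, n_true = n_true,
           ppv = ppv, ppv_low = ppv_ci$low, ppv_high = ppv_ci$high,
           n_gold = n_gold, sensitivity = sens,
           sensitivity_low = sens_ci$low, sensitivity_high = sens_ci$high)
  })
  structure(rows, class = c("ipf_validation", class(rows)),
            gold = gold, level = level)
}

new_concordance <- function(counts, source_names = c("aurum", "hes", "ons")) {
  regions <- c("aurum_only", "hes_only", "ons_only", "aurum_hes",
               "aurum_ons", "hes_ons", "all_three")
  stopifnot(identical(names(counts), regions))
  x <- tibble(region = regions, n = as.numeric(counts))
  marg <- c(
    aurum = counts[["aurum_only"]] + counts[["aurum_hes"]] +
      counts[["aurum_ons"]] + counts[["all_three"]],
    hes = counts[["hes_only"]] + counts[["aurum_hes"]] +
      counts[["hes_ons"]] + counts[["all_three"]],
    ons = counts[["ons_only"]] + counts[["aurum_ons"]] +
      counts[["hes_ons"]] + counts[["all_three"]])
  structure(x, class = c("ipf_concordance", class(x)),
            total = sum(x$n), marginals = marg, sources = source_names)
}

#' Three-source concordance partition
#'
#' Partitions the union of three patient-identifier sets into the seven
#' exclusive membership regions: each source alone, each pair, and all
#' three. Region counts always sum to the union size and the source
#' marginals are recovered exactly.
#'
#' @param aurum_ids,hes_ids,ons_ids Character vectors of patient ids (the
#'   primary-care, hospital and death-registration cohorts).
#' @return A tibble of class `ipf_concordance` with columns `region`, `n`
#'   and attributes `total` and `marginals`.
#' @examples
#' concordance(c("a", "b"), c("b", "c"), c("b", "d"))
#' @export
concordance <- function(aurum_ids, hes_ids, ons_ids) {
  a <- unique(aurum_ids); h <- unique(hes_ids); o <- unique(ons_ids)
  all_ids <- unique(c(a, h, o))
  in_a <- all_ids %in% a; in_h <- all_ids %in% h; in_o <- all_ids %in% o
  counts <- c(
    aurum_only = sum(in_a & !in_h & !in_o),
    hes_only = sum(!in_a & in_h & !in_o),
    ons_only = sum(!in_a & !in_h & in_o),
    aurum_hes = sum(in_a & in_h & !in_o),
    aurum_ons = sum(in_a & !in_h & in_o),
    hes_ons = sum(!in_a & in_h & in_o),
    all_three = sum(in_a & in_h & in_o))
  new_concordance(counts)
}

#' @export
print.ipf_concordance <- function(x, ...) {
  m <- attr(x, "marginals")
  cat(sprintf("<concordance partition> total %s (aurum %s, hes %s, ons %s)\n",
              format(attr(x, "total"), big.mark = ","),
              format(m[["aurum"]], big.mark = ","),
              format(m[["hes"]], big.mark = ","),
              format(m[["ons"]], big.mark = ",")))
  NextMethod()
}

#' Membership sets behind the concordance analysis
#'
#' Builds the three patient-id sets the concordance partition compares,
#' restricted to study-eligible patients who died within the study period:
#' the primary-care set (at least one broad code before death or within the
#' post-death grace period), the hospital set (a qualifying admission in
#' the follow-up window, under the given position rule), and the
#' death-registration set (IPF on the certificate under `gold`).
#'
#' @param features Output of [patient_features()].
#' @param config A [study_config()] (supplies the grace period).
#' @param gold `"anywhere"` or `"underlying_only"` for the death set.
#' @param position_rule Position rule for the hospital set.
#' @return A named list of character vectors: `aurum`, `hes`, `ons`.
#' @export
membership_sets <- function(features, config = study_config(),
                            gold = c("anywhere", "underlying_only"),
                            position_rule = "primary_or_secondary") {
  gold <- match.arg(gold)
  adm_col <- paste0("adm_", c(primary_or_secondary = "ps", top3 = "top3",
                              any_position = "any")[[position_rule]])
  pool <- features |>
    filter(.data$eligible, .data$deceased,
           .data$death_date >= config$study_start,
           .data$death_date <= config$study_end)
  aurum <- pool |>
    filter(!is.na(.data$broad_date),
           .data$broad_date <= .data$death_date + config$death_grace_days)
  hes <- pool |> filter(!is.na(.data[[adm_col]]))
  gold_col <- if (gold == "anywhere") "ipf_death_any" else "ipf_death_underlying"
  ons <- pool |> filter(.data[[gold_col]])
  list(aurum = aurum$patient_id, hes = hes$patient_id, ons = ons$patient_id)
}

#' Concordance partition of a linked cohort
#'
#' @param cohort A [linked_cohort()], or `NULL` if `features` is given.
#' @inheritParams membership_sets
#' @param features Optional precomputed [patient_features()].
#' @param ... Passed to [patient_features()].
#' @return An `ipf_concordance` (see [concordance()]).
#' @export
cohort_concordance <- function(cohort, config = study_config(),
                               gold = "anywhere",
                               position_rule = "primary_or_secondary",
                               features = NULL, ...) {
  if (is.null(features)) features <- patient_features(cohort, config = config, ...)
  sets <- membership_sets(features, config, gold, position_rule)
  concordance(sets$aurum, sets$hes, sets$ons)
}

#' Derive the full seven-region partition from printed marginals
#'
#' Given the union size, the three source totals, two pairwise
#' intersections involving the death-registration set, the triple
#' intersection and (optionally, as a consistency check) the
#' either-primary-care-or-hospital coverage of the death set, solves the
#' remaining region — the primary-care/hospital intersection — by
#' inclusion–exclusion and returns the full exclusive partition.
#' Infeasible inputs (any derived region negative) raise an error naming
#' the violated region.
#'
#' @param total Size of the three-set union.
#' @param aurum,hes,ons The three source totals.
#' @param aurum_ons,hes_ons Pairwise intersection sizes with the death set.
#' @param all_three Triple intersection size.
#' @param either_in_ons Optional `|(Aurum or HES) and ONS|` for a
#'   consistency check.
#' @return An `ipf_concordance`.
#' @examples
#' p <- derive_pairwise_from_marginals(17559, 9498, 10714, 11295,
#'                                     6113, 6651, 4304, 8460)
#' attr(p, "marginals")
#' @export
derive_pairwise_from_marginals <- function(total, aurum, hes, ons,
                                           aurum_ons, hes_ons, all_three,
                                           either_in_ons = NULL) {
  aurum_hes <- aurum + hes + ons - aurum_ons - hes_ons + all_three - total
  counts <- c(
    aurum_only = aurum - aurum_hes - aurum_ons + all_three,
    hes_only = hes - aurum_hes - hes_ons + all_three,
    ons_only = ons - aurum_ons - hes_ons + all_three,
    aurum_hes = aurum_hes - all_three,
    aurum_ons = aurum_ons - all_three,
    hes_ons = hes_ons - all_three,
    all_three = all_three)
  neg <- counts < 0
  if (any(neg)) {
    abort(sprintf("infeasible marginals: region '%s' would be %d",
                  names(counts)[neg][1], counts[neg][1]),
          class = "ipfvalid_infeasible_error")
  }
  if (!is.null(either_in_ons) &&
      aurum_ons + hes_ons - all_three != either_in_ons) {
    abort(sprintf("inconsistent marginals: (Aurum or HES) in ONS is %d, stated %d",
                  aurum_ons + hes_ons - all_three, either_in_ons),
          class = "ipfvalid_infeasible_error")
  }
  new_concordance(counts)
}

#' Gold-standard sensitivity analysis
#'
#' Recomputes the concordance partition with the death-registration set
#' restricted from IPF-anywhere-on-certificate to IPF-as-underlying-cause,
#' and reports the coverage proportions that shift with it: the share of
#' the primary-care cohort confirmed in the death data, the share of the
#' hospital cohort confirmed, and the triple-region share of the (new)
#' study population.
#'
#' @inheritParams cohort_concordance
#' @return A list with elements `anywhere` and `underlying_only` (each an
#'   `ipf_concordance`) and `summary`, a tibble comparing the two modes.
#' @export
sensitivity_analysis_gold <- function(cohort, config = study_config(),
                                      features = NULL, ...) {
  if (is.null(features)) features <- patient_features(cohort, config = config, ...)
  out <- lapply(c(anywhere = "anywhere", underlying_only = "underlying_only"),
                function(g) {
                  sets <- membership_sets(features, config, g)
                  list(sets = sets, part = concordance(sets$aurum, sets$hes, sets$ons))
                })
  summarise_mode <- function(m, mode) {
    part <- m$part
    tab <- stats::setNames(part$n, part$region)
    n_a <- length(m$sets$aurum); n_h <- length(m$sets$hes)
    tibble(gold = mode,
           total = attr(part, "total"),
           n_ons = attr(part, "marginals")[["ons"]],
           aurum_ons = tab[["aurum_ons"]] + tab[["all_three"]],
           hes_ons = tab[["hes_ons"]] + tab[["all_three"]],
           all_three = tab[["all_three"]],
           prop_aurum_confirmed = (tab[["aurum_ons"]] + tab[["all_three"]]) / n_a,
           prop_hes_confirmed = (tab[["hes_ons"]] + tab[["all_three"]]) / n_h,
           prop_all_three = tab[["all_three"]] / attr(part, "total"))
  }
  list(anywhere = out$anywhere$part,
       underlying_only = out$underlying_only$part,
       summary = bind_rows(summarise_mode(out$anywhere, "anywhere"),
                           summarise_mode(out$underlying_only, "underlying_only")))
}

#' Position-rule sensitivity analysis
#'
#' Recomputes the hospital cohort with qualifying ICD-10 codes allowed in
#' the top three diagnostic positions instead of the first two, and
#' reports the new cohort size together with the share of each cohort that
#' also has an IPF death record. Relaxing the rule can only add patients.
#'
#' @inheritParams cohort_concordance
#' @return A tibble with one row per position rule: `position_rule`,
#'   `n_hes`, `n_hes_ons`, `prop_hes_confirmed`.
#' @export
sensitivity_analysis_positions <- function(cohort, config = study_config(),
                                           features = NULL, ...) {
  if (is.null(features)) features <- patient_features(cohort, config = config, ...)
  purrr::map_dfr(c("primary_or_secondary", "top3"), function(rule) {
    sets <- membership_sets(features, config, "anywhere", position_rule = rule)
    n_hes <- length(sets$hes)
    n_both <- length(intersect(sets$hes, sets$ons))
    tibble(position_rule = rule, n_hes = n_hes, n_hes_ons = n_both,
           prop_hes_confirmed = if (n_hes > 0) n_both / n_hes else NA_real_)
  })
}
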