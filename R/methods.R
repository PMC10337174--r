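#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
#' @method tidy ipf_validation
#' @rdname ipfvalid-broom
#' @param x An `ipf_validation` or `ipf_concordance` object.
#' @param ... Unused.
tidy.ipf_validation <- function(x, ...) {
  as_tibble(x)
}

#' Broom-style accessors for result objects
#'
#' `tidy()` returns the per-row results as a plain tibble; `glance()` a
#' one-row summary (gold-standard mode and shared denominator for a
#' validation, totals and marginals for a concordance partition).
#'
#' @name ipfvalid-broom
#' @export
#' @method glance ipf_validation
glance.ipf_validation <- function(x, ...) {
  tibble(n_algorithms = nrow(x), gold = attr(x, "gold"),
         level = attr(x, "level"),
         n_gold = if (nrow(x)) x$n_gold[1] else NA_integer_)
}

#' @export
#' @method tidy ipf_concordance
#' @rdname ipfvalid-broom
tidy.ipf_concordance <- function(x, ...) {
  as_tibble(x) |> mutate(share = .data$n / attr(x, "total"))
}

#' @export
#' @method glance ipf_concordance
#' @rdname ipfvalid-broom
glance.ipf_concordance <- function(x, ...) {
  m <- attr(x, "marginals")
  tibble(total = attr(x, "total"), aurum = m[["aurum"]], hes = m[["hes"]],
         ons = m[["ons"]])
}

#' Plot algorithm validation results
#'
#' Point estimates with Wilson interval bars for PPV and sensitivity, one
#' panel per metric.
#'
#' @param object An `ipf_validation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot ipf_validation
autoplot.ipf_validation <- function(object, ...) {
  long <- bind_rows(
    tibble(algorithm_id = object$algorithm_id, metric = "PPV",
           estimate = object$ppv, low = object$ppv_low, high = object$ppv_high),
    tibble(algorithm_id = object$algorithm_id, metric = "Sensitivity",
           estimate = object$sensitivity, low = object$sensitivity_low,
           high = object$sensitivity_high))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$algorithm_id,
                                     y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$low, ymax = .data$high)) +
    ggplot2::facet_wrap(~metric, ncol = 1) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Diagnostic algorithm", y = NULL,
                  title = "Case-finding validation against death records") +
    ggplot2::theme_minimal()
}

#' Plot a concordance partition
#'
#' @param object An `ipf_concordance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot ipf_concordance
autoplot.ipf_concordance <- function(object, ...) {
  d <- tidy(object)
  d$region <- factor(d$region, levels = d$region)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", 100 * .data$share)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Patients",
                  title = "Three-source recording concordance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot yearly code-usage trends
#'
#' @param object An `ipf_trend` from [code_usage_by_year()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot ipf_trend
autoplot.ipf_trend <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$share,
                                       colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "Year", y = "Share of coded consultations",
                  colour = "Code term",
                  title = "Primary-care IPF code usage over time") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
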