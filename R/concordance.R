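# Morphology-versus-genetics concordance: per-metric ordinary least squares
# (genetic y on morphological x, log-linearized for the IOBS) and
# quality-class agreement tables.

#' Log-linearize paired IOBS values
#'
#' Natural log applied elementwise to both the morphological and genetic
#' IOBS series before regression. Pairs with a non-positive or undefined
#' value in either series are excluded with a warning listing the sites.
#'
#' @param pairs Tibble (site_id, x, y).
#' @return The transformed pairs; excluded sites in attribute
#'   `excluded_sites`.
#' @export
log_linearize <- function(pairs) {
  bad <- !is.finite(pairs$x) | !is.finite(pairs$y) |
    pairs$x <= 0 | pairs$y <= 0
  if (any(bad)) {
    warning("sites excluded from log-linearization: ",
            paste(pairs$site_id[bad], collapse = ", "))
  }
  out <- pairs[!bad, , drop = FALSE]
  out$x <- log(out$x); out$y <- log(out$y)
  attr(out, "excluded_sites") <- pairs$site_id[bad]
  out
}

#' Regression of genetic on morphological metric values
#'
#' Ordinary least squares y = a x + b with the coefficient of determination
#' (squared Pearson correlation) and the two-sided Pearson-test p-value from
#' t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom. For `metric_name =
#' "iobs"` the pairs are log-linearized first.
#'
#' @param pairs Tibble (site_id, x, y): x morphological, y genetic.
#' @param metric_name Label for the metric; `"iobs"` triggers the log
#'   transform.
#' @return A `concordance_fit` object; see [tidy.concordance_fit()] and
#'   [glance.concordance_fit()].
#' @export
concordance_regression <- function(pairs, metric_name = "metric") {
  pairs <- tibble::as_tibble(pairs)
  pairs <- pairs[is.finite(pairs$x) & is.finite(pairs$y), , drop = FALSE]
  if (identical(metric_name, "iobs")) pairs <- log_linearize(pairs)
  n <- nrow(pairs)
  if (n < 3) stop("insufficient pairs")
  if (length(unique(pairs$x)) < 2) stop("degenerate predictor")
  fit <- lm(y ~ x, data = pairs)
  r <- suppressWarnings(stats::cor(pairs$x, pairs$y))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  structure(list(metric = metric_name, n = n,
                 slope = unname(coef(fit)["x"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 r_squared = r^2, pearson_p = p,
                 lm = fit, pairs = pairs),
            class = "concordance_fit")
}

#' @export
print.concordance_fit <- function(x, ...) {
  cat(sprintf(
    "concordance_fit [%s]: n = %d, slope = %.3f, intercept = %.3f,\n  R^2 = %.3f, Pearson p = %.3g\n",
    x$metric, x$n, x$slope, x$intercept, x$r_squared, x$pearson_p))
  invisible(x)
}

#' Tidy a concordance fit
#'
#' @param x A `concordance_fit`.
#' @param ... Unused.
#' @return One row per coefficient: term, estimate, std.error, statistic,
#'   p.value.
#' @export
tidy.concordance_fit <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = unname(sm[, 1]),
                 std.error = unname(sm[, 2]),
                 statistic = unname(sm[, 3]),
                 p.value = unname(sm[, 4]))
}

#' One-row summary of a concordance fit
#'
#' @param x A `concordance_fit`.
#' @param ... Unused.
#' @return Tibble: metric, n, slope, intercept, r_squared, pearson_p.
#' @export
glance.concordance_fit <- function(x, ...) {
  tibble::tibble(metric = x$metric, n = x$n, slope = x$slope,
                 intercept = x$intercept, r_squared = x$r_squared,
                 pearson_p = x$pearson_p)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Quality-class agreement between morphological and genetic diagnoses
#'
#' Classes are compared on the ordered scale bad < poor < medium < good <
#' very_good. Sites with an undefined class in either source are reported
#' in their own category.
#'
#' @param morph,genetic Tibbles (site_id, quality_class) over the same site
#'   set.
#' @return List: `per_site` tibble (site_id, morph, genetic, delta,
#'   agreement) and `counts` tibble over `identical` / `genetic_higher` /
#'   `genetic_lower` / `undefined`.
#' @export
class_agreement <- function(morph, genetic) {
  if (!setequal(morph$site_id, genetic$site_id) ||
      nrow(morph) != nrow(genetic)) {
    stop("unpaired sites")
  }
  g <- genetic[match(morph$site_id, genetic$site_id), , drop = FALSE]
  mo <- quality_factor(as.character(morph$quality_class))
  ge <- quality_factor(as.character(g$quality_class))
  mi <- match(as.character(mo), QUALITY_LEVELS)
  gi <- match(as.character(ge), QUALITY_LEVELS)
  delta <- gi - mi
  agreement <- ifelse(is.na(delta), "undefined",
               ifelse(delta == 0, "identical",
               ifelse(delta > 0, "genetic_higher", "genetic_lower")))
  per_site <- tibble::tibble(site_id = morph$site_id, morph = mo,
                             genetic = ge, delta = delta,
                             agreement = agreement)
  counts <- per_site |>
    dplyr::count(agreement = factor(.data$agreement,
                                    levels = c("identical", "genetic_higher",
                                               "genetic_lower", "undefined")),
                 name = "n", .drop = FALSE)
  list(per_site = per_site, counts = counts)
}
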