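#' Pearson correlation with linear fit
#'
#' Pearson's r computed from the covariance definition, with a two-sided
#' p-value from the t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n - 2
#' degrees of freedom, plus the least-squares slope and intercept of
#' `y ~ x`. This is the correlation statistic used throughout the
#' descriptor-response and trajectory-response analyses.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return An object of class `nanosar_cor`; use [tidy()] or [glance()]
#'   for a one-row tibble with `n`, `r`, `r_squared`, `p_value`, `slope`,
#'   `intercept`.
#' @examples
#' tidy(pearson_cor(1:5, c(1.1, 2.0, 2.9, 4.2, 5.1)))
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort(sprintf("need at least 3 complete pairs, got %d", n))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0 || syy == 0) abort("zero variance in x or y")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  slope <- sxy / sxx
  structure(
    list(n = n, r = r, r_squared = r^2, p_value = p,
         slope = slope, intercept = mean(y) - slope * mean(x)),
    class = "nanosar_cor")
}

#' @export
tidy.nanosar_cor <- function(x, ...) {
  tibble(n = x$n, r = x$r, r_squared = x$r_squared,
         p_value = x$p_value, slope = x$slope, intercept = x$intercept)
}

#' @export
glance.nanosar_cor <- function(x, ...) tidy(x)

#' @export
print.nanosar_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f (r^2 = %.3f), p = %.3g, n = %d\n",
              x$r, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Correlate optical responses with molecular descriptors
#'
#' Joins a response table with a descriptor table on `analyte_id` and
#' computes, per descriptor field, the Pearson correlation between the
#' normalized response and the descriptor. Analytes lacking a descriptor
#' value are dropped pairwise (not imputed) and counted in the output, so
#' each field is analyzed on its own complete subset, mirroring how the
#' screen is analyzed over overlapping compound subsets. No multiple
#' testing correction is applied by default; `adjust = "bonferroni"`
#' adds an adjusted column.
#'
#' @param responses Data frame with `analyte_id` and the response column.
#' @param descriptors Data frame with `analyte_id` and descriptor columns
#'   (e.g. `hammett_sigma`, `e_homo`, `e_red`).
#' @param fields Character vector of descriptor column names to test.
#' @param response_col Response column name (default `"normalized"`).
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return Tibble, one row per field: `field`, `n`, `n_dropped`, `r`,
#'   `r_squared`, `p_value`, `slope`, `intercept`.
#' @export
correlate_descriptors <- function(responses, descriptors, fields,
                                  response_col = "normalized",
                                  adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  check_columns(responses, c("analyte_id", response_col), "responses")
  check_columns(descriptors, c("analyte_id", fields), "descriptors")
  if (anyDuplicated(descriptors$analyte_id)) {
    abort("descriptor analyte_id values must be unique")
  }
  joined <- inner_join(responses, descriptors, by = "analyte_id")
  out <- purrr::map_dfr(fields, function(f) {
    x <- joined[[f]]
    y <- joined[[response_col]]
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) < 3) {
      abort(sprintf(
        "descriptor '%s': only %d complete pairs after join (need >= 3)",
        f, sum(keep)))
    }
    res <- tidy(pearson_cor(x[keep], y[keep]))
    dplyr::bind_cols(tibble(field = f, n_dropped = sum(!keep)), res)
  })
  out <- select(out, "field", "n", "n_dropped", dplyr::everything())
  if (adjust == "bonferroni") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  }
  out
}

#' Unpaired two-sample t test
#'
#' Two-sided test for a difference in means between two analyte groups
#' (e.g. positively charged vs neutral analytes). Equal-variance Student's
#' t by default; `welch = TRUE` uses the Welch correction.
#'
#' @param group_a,group_b Numeric vectors, each with n >= 2.
#' @param welch Use Welch's unequal-variance t test.
#' @return One-row tibble: `t_statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @export
unpaired_t_test <- function(group_a, group_b, welch = FALSE) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 finite values")
  }
  fit <- t.test(group_a, group_b, var.equal = !welch)
  tibble(t_statistic = unname(fit$statistic), df = unname(fit$parameter),
         p_value = fit$p.value, mean_a = mean(group_a),
         mean_b = mean(group_b),
         n_a = length(group_a), n_b = length(group_b))
}

#' Structural heuristic for sensor response
#'
#' The necessary-condition rule distilled from the screen: an analyte can
#' elicit an optical response only if it carries vicinal (ortho)
#' hydrogen-bond donors on a pi-conjugated scaffold. Moving the donors to
#' meta positions, or removing conjugation, abolishes the response. The
#' rule is necessary, not sufficient: satisfying it does not guarantee a
#' response.
#'
#' @param descriptors Data frame with logical columns `has_vicinal_donors`
#'   and `conjugated`.
#' @return Logical vector, one element per row.
#' @export
heuristic_response_rule <- function(descriptors) {
  check_columns(descriptors, c("has_vicinal_donors", "conjugated"),
                "descriptors")
  hv <- descriptors$has_vicinal_donors
  cj <- descriptors$conjugated
  if (any(is.na(hv)) || any(is.na(cj))) {
    abort("has_vicinal_donors / conjugated must not contain missing values")
  }
  hv & cj
}
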