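#' Tidy a Mann-Whitney U test
#'
#' @param x A `mwu_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `p.value`, `method`,
#'   `n.x`, `n.y`, `ties`, `verdict` (Bonferroni-banded with the default
#'   divisor 6).
#' @method tidy mwu_test
#' @export
tidy.mwu_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method,
         n.x = unname(x$n[1]), n.y = unname(x$n[2]), ties = x$ties,
         verdict = bonferroni_verdict(x$p_value))
}

#' @rdname tidy.mwu_test
#' @method glance mwu_test
#' @export
glance.mwu_test <- function(x, ...) tidy.mwu_test(x, ...)

#' Tidy a Kruskal-Wallis test
#'
#' @param x A `kw_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `statistic` (H), `df`, `p.value`,
#'   `n.groups`, `verdict`.
#' @method tidy kw_test
#' @export
tidy.kw_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
         n.groups = length(x$n_per_group),
         verdict = bonferroni_verdict(x$p_value))
}

#' @rdname tidy.kw_test
#' @method glance kw_test
#' @export
glance.kw_test <- function(x, ...) tidy.kw_test(x, ...)

#' Tidy a LOESS profile fit
#'
#' `tidy()` returns the fitted curve (one row per grid point); `glance()`
#' returns a one-row fit summary.
#'
#' @param x A `loess_profile` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy loess_profile
#' @export
tidy.loess_profile <- function(x, ...) x$fitted

#' @rdname tidy.loess_profile
#' @method glance loess_profile
#' @export
glance.loess_profile <- function(x, ...) {
  tibble(span = x$span, degree = x$degree, kernel = x$kernel, n = x$n,
         enp = x$model$enp, residual.sd = x$model$s)
}
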