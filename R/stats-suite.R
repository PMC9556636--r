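#' Exact Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U test between two independent samples. For the
#' small group sizes of an ablation series (n = 6 per cell) the exact null
#' distribution is computed by dynamic programming over the midrank
#' multiset — equivalent to full enumeration of all `choose(n + m, n)` rank
#' assignments and valid in the presence of ties (midranks) where the
#' classical exact tables are not. The two-sided p-value doubles the smaller
#' tail, capped at 1.
#'
#' @param x,y Non-empty numeric samples.
#' @param method `"auto"` (exact when the pooled size allows it, i.e.
#'   n + m <= 40), `"exact"`, or `"normal"` (tie-corrected normal
#'   approximation with continuity correction).
#' @return An object of class `mwu_test`: a list with `statistic` (U of
#'   `x`), `p_value`, `method`, `n`, `ties`. Supports [tidy()] and
#'   [glance()].
#' @examples
#' mwu_exact(c(1, 2, 3), c(4, 5, 6))$p_value # 0.1
#' @export
mwu_exact <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    stop_data("both samples must be non-empty")
  }
  if (any(!is.finite(c(x, y)))) stop_data("samples must be finite")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))  # midranks
  ties <- anyDuplicated(c(x, y)) > 0
  wx <- sum(r[seq_len(n)])
  u <- wx - n * (n + 1) / 2

  if (method == "auto") method <- if (N <= 40) "exact" else "normal"
  if (method == "exact" && N > 60) {
    stop_parameter("exact method is limited to n + m <= 60; use method = \"normal\"")
  }

  if (method == "exact") {
    p <- mwu_exact_p(r, n, wx)
  } else {
    mu <- n * m / 2
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  structure(list(statistic = u, p_value = p, method = method,
                 n = c(n = n, m = m), ties = ties),
            class = "mwu_test")
}

# Exact two-sided p by DP over the midrank multiset: the count of
# n-subsets of the pooled ranks attaining each possible rank sum (doubled
# ranks keep sums integral under midranks).
mwu_exact_p <- function(r, n, wx) {
  w2 <- as.integer(round(2 * r))
  N <- length(w2)
  S <- sum(w2)
  counts <- matrix(0, nrow = n + 1, ncol = S + 1)
  counts[1, 1] <- 1
  for (i in seq_len(N)) {
    v <- w2[i]
    kmax <- min(n, i)
    for (k in kmax:1) {
      counts[k + 1, (v + 1):(S + 1)] <-
        counts[k + 1, (v + 1):(S + 1)] + counts[k, 1:(S + 1 - v)]
    }
  }
  dist <- counts[n + 1, ]
  total <- sum(dist)
  w2x <- as.integer(round(2 * wx))
  p_le <- sum(dist[seq_len(w2x + 1)]) / total
  p_ge <- sum(dist[(w2x + 1):(S + 1)]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Kruskal-Wallis rank-sum test across several groups
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H statistic,
#' chi-square reference with k - 1 df) returning a tidy-friendly object.
#'
#' @param groups A list of two or more non-empty numeric samples; names are
#'   used as group labels.
#' @return An object of class `kw_test` with `statistic` (H), `df`,
#'   `p_value`, `n_per_group`, `group_labels`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))$statistic
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop_data("need a list of at least 2 groups")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop_data("all groups must be non-empty")
  labels <- names(groups) %||% paste0("group", seq_along(groups))
  pooled <- unlist(groups)
  if (any(!is.finite(pooled))) stop_data("all group values must be finite")
  if (length(unique(pooled)) == 1) {
    # fully tied data carry no rank information: H = 0 by convention
    return(structure(list(statistic = 0, df = length(groups) - 1L,
                          p_value = 1, n_per_group = as.integer(sizes),
                          group_labels = labels),
                     class = "kw_test"))
  }
  kt <- kruskal.test(groups)
  structure(list(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value,
                 n_per_group = as.integer(sizes),
                 group_labels = labels),
            class = "kw_test")
}

#' Bonferroni-banded significance verdict
#'
#' Classifies a p-value against a Bonferroni-adjusted two-sided significance
#' level `0.05 / n_comparisons`, with p-values between that level and 0.05
#' reported as a trend. The default divisor 6 corresponds to comparing each
#' perfused flow rate against the no-flow series within one A-V distance
#' (adjusted level 0.05 / 6 = 0.0083).
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param n_comparisons Size of the comparison family (>= 1, default 6).
#' @return Character vector: `"significant"`, `"trend"` or
#'   `"not_significant"`.
#' @examples
#' bonferroni_verdict(c(0.002, 0.03, 0.5)) # significant, trend, not_significant
#' @export
bonferroni_verdict <- function(p, n_comparisons = 6) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_data("`p` must lie in [0, 1]")
  }
  if (!is.finite(n_comparisons) || n_comparisons < 1) {
    stop_parameter("`n_comparisons` must be >= 1")
  }
  alpha_sig <- 0.05 / n_comparisons
  ifelse(p <= alpha_sig, "significant",
         ifelse(p <= 0.05, "trend", "not_significant"))
}

#' LOESS smoothing of a cooling-type profile
#'
#' Locally weighted polynomial regression (tricube weights on the
#' span-nearest neighbours, via [stats::loess()] with exact direct fitting)
#' evaluated on a regular grid.
#'
#' @param x,y Numeric vectors (at least `degree + 2` points).
#' @param span Neighbourhood fraction in `(0, 1]` (default 0.5).
#' @param degree Local polynomial degree, 1 or 2.
#' @param n_grid Number of evaluation points (ignored when `x_grid` given).
#' @param x_grid Optional explicit evaluation grid.
#' @return An object of class `loess_profile`: `fitted` (tibble with
#'   `x`, `y`), `span`, `degree`, `kernel`, `n`, and the underlying `model`.
#'   Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @examples
#' f <- loess_fit(1:20, (1:20) / 2, span = 0.75)
#' tidy(f)
#' @export
loess_fit <- function(x, y, span = 0.5, degree = 1, n_grid = 100,
                      x_grid = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_data("`x` and `y` lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_data("inputs must be finite")
  if (!degree %in% c(1, 2)) stop_parameter("`degree` must be 1 or 2")
  if (!is.finite(span) || span <= 0 || span > 1) {
    stop_parameter("`span` must lie in (0, 1]")
  }
  if (length(x) < degree + 2) {
    stop_data(sprintf("need at least %d points for degree %d", degree + 2, degree))
  }
  grid <- x_grid %||% seq(min(x), max(x), length.out = n_grid)
  fit <- tryCatch(
    stats::loess(y ~ x, span = span, degree = degree, family = "gaussian",
                 surface = "direct",
                 data = data.frame(x = x, y = y)),
    error = function(e) {
      stop_mwacool(paste0("loess fitting failed: ", conditionMessage(e)),
                   "mwacool_fitting_error")
    })
  pred <- predict(fit, newdata = data.frame(x = grid))
  if (any(!is.finite(pred))) {
    bad <- grid[!is.finite(pred)][1]
    stop_mwacool(sprintf(
      "insufficient points in the local window at grid point %.4g", bad),
      "mwacool_fitting_error")
  }
  structure(list(fitted = tibble(x = grid, y = as.numeric(pred)),
                 span = span, degree = degree, kernel = "tricube",
                 n = length(x), model = fit),
            class = "loess_profile")
}

#' Compare perfused series against the no-flow baseline
#'
#' For each A-V distance, tests every perfused flow rate against the no-flow
#' series with the exact Mann-Whitney U test and attaches the
#' Bonferroni-banded verdict (divisor = number of perfused flows per
#' distance, by default).
#'
#' @param reports A [stack_reports()] tibble.
#' @param response Column to compare (default `"ablation_volume_ml"`).
#' @param baseline_flow Baseline flow rate (default 0).
#' @param n_comparisons Bonferroni family size; defaults to the number of
#'   perfused flows within each distance.
#' @return A tibble with one row per (distance, flow): group sizes, U,
#'   p-value and verdict.
#' @examples
#' study <- simulate_study(study_design(5, c(0, 500), replicates = 3), seed = 1)
#' reports <- stack_reports(measure_slices(study$slices))
#' flow_comparisons(reports)
#' @export
flow_comparisons <- function(reports, response = "ablation_volume_ml",
                             baseline_flow = 0, n_comparisons = NULL) {
  if (!response %in% names(reports)) {
    stop_data(sprintf("column `%s` not found in reports", response))
  }
  if (!baseline_flow %in% reports$flow_ml_min) {
    stop_data(sprintf("no baseline runs at flow %g ml/min", baseline_flow))
  }
  flows <- sort(setdiff(unique(reports$flow_ml_min), baseline_flow))
  n_comparisons <- n_comparisons %||% length(flows)
  out <- purrr::map_dfr(sort(unique(reports$av_distance_mm)), function(d) {
    base <- reports[[response]][reports$av_distance_mm == d &
                                  reports$flow_ml_min == baseline_flow]
    purrr::map_dfr(flows, function(q) {
      trt <- reports[[response]][reports$av_distance_mm == d &
                                   reports$flow_ml_min == q]
      test <- mwu_exact(trt, base)
      tibble(av_distance_mm = d, flow_ml_min = q, response = response,
             n_flow = length(trt), n_baseline = length(base),
             statistic = test$statistic, p_value = test$p_value,
             verdict = bonferroni_verdict(test$p_value, n_comparisons))
    })
  })
  out
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %g, n = %d/%d, p = %.4g%s\n",
              x$method, x$statistic, x$n[1], x$n[2], x$p_value,
              if (x$ties) " (midrank ties)" else ""))
  invisible(x)
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (groups: %s)\n",
              x$statistic, x$df, x$p_value,
              paste(x$group_labels, collapse = ", ")))
  invisible(x)
}
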