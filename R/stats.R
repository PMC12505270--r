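#' Distribution-free confidence interval for a median
#'
#' Order-statistic (binomial) interval with Hettmansperger-Sheather
#' interpolation: the conservative bracket `(x_(k), x_(n-k+1))` and the
#' next inner bracket are blended so the interval's coverage approximates
#' the nominal level instead of overshooting it.  For very small samples
#' the interval falls back to the sample range.
#'
#' @param x numeric sample.
#' @param conf nominal coverage (default 0.95).
#' @return list: `median`, `lower`, `upper`, `coverage` (coverage of the
#'   conservative outer bracket).
#' @export
median_ci <- function(x, conf = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(list(median = NA_real_, lower = NA_real_,
                          upper = NA_real_, coverage = NA_real_))
  alpha <- (1 - conf) / 2
  k <- stats::qbinom(alpha, n, 0.5)
  if (stats::pbinom(k - 1, n, 0.5) > alpha) k <- k - 1
  k <- max(1L, k)
  cov_outer <- 1 - 2 * stats::pbinom(k - 1, n, 0.5)
  if (k + 1 > n - k) {
    return(list(median = stats::median(x), lower = x[k],
                upper = x[n - k + 1L], coverage = cov_outer))
  }
  cov_inner <- 1 - 2 * stats::pbinom(k, n, 0.5)
  lam <- if (cov_outer > conf && conf > cov_inner) {
    (1 + (k * (conf - cov_inner)) /
       ((n - k) * (cov_outer - conf)))^-1
  } else 0
  lam <- min(max(lam, 0), 1)
  list(median = stats::median(x),
       lower = (1 - lam) * x[k] + lam * x[k + 1L],
       upper = (1 - lam) * x[n - k + 1L] + lam * x[n - k],
       coverage = cov_outer)
}

#' Compare two groups with the Wilcoxon rank-sum test
#'
#' Reports each group's median with a distribution-free 95% CI and the
#' two-sided rank-sum p-value (exact when the smaller group has at most 8
#' observations and there are no ties; normal approximation with tie
#' correction otherwise).  By default each group is first cleaned of
#' outliers with ROUT at Q = 1% (see [rout_outliers()]).
#'
#' @param a,b numeric samples.
#' @param labels length-2 character group labels.
#' @param rout_filter apply the ROUT pre-filter per group.
#' @param Q ROUT false-discovery coefficient.
#' @param conf confidence level for the median CIs.
#' @return list of class `group_comparison`: `table` (per-group label, n,
#'   median, CI bounds, outliers removed), `p_value`, `method`.
#' @export
wilcoxon_compare <- function(a, b, labels = c("a", "b"),
                             rout_filter = TRUE, Q = 0.01, conf = 0.95) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  removed <- c(0L, 0L)
  if (rout_filter) {
    if (length(a) >= 3) {
      out <- rout_outliers(a, Q); removed[1] <- sum(out); a <- a[!out]
    }
    if (length(b) >= 3) {
      out <- rout_outliers(b, Q); removed[2] <- sum(out); b <- b[!out]
    }
  }
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs at least 3 values after outlier filtering")
  }
  ties <- any(duplicated(c(a, b)))
  all_tied <- length(unique(c(a, b))) == 1L
  if (all_tied) {
    warning("all values tied across both groups; p set to 1")
    p <- 1
    method <- "degenerate (all values tied)"
  } else {
    exact <- min(length(a), length(b)) <= 8 && !ties
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    p <- ht$p.value
    method <- if (exact) "exact rank-sum" else
      "normal approximation with tie correction"
  }
  ca <- median_ci(a, conf)
  cb <- median_ci(b, conf)
  structure(list(
    table = data.frame(
      group = labels,
      n = c(length(a), length(b)),
      median = c(ca$median, cb$median),
      ci_lower = c(ca$lower, cb$lower),
      ci_upper = c(ca$upper, cb$upper),
      outliers_removed = removed,
      outlier_method = if (rout_filter)
        sprintf("ROUT Q=%g%%", 100 * Q) else "none"
    ),
    p_value = p,
    method = method
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("two-sided Wilcoxon rank-sum p = %.4g (%s)\n",
              x$p_value, x$method))
  invisible(x)
}

# D'Agostino-Pearson omnibus normality test (skewness + kurtosis K^2).
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 20) stop("D'Agostino-Pearson K^2 requires n >= 20")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2

  # skewness (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis (Anscombe-Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - eb2) / sqrt(vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Normality test suite
#'
#' Runs the four normality tests commonly reported together —
#' D'Agostino-Pearson omnibus K^2, Shapiro-Wilk, Anderson-Darling and
#' Lilliefors-corrected Kolmogorov-Smirnov — and reports their p-values.
#' The suite is informational: downstream comparisons are nonparametric
#' regardless of the outcome.  Tests whose sample-size requirements are
#' not met (or degenerate samples) are marked unavailable with a note.
#'
#' @param values numeric sample (n >= 8).
#' @return data frame: `test`, `statistic`, `p_value`, `note`.
#' @export
normality_suite <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 8) stop("normality suite requires n >= 8")
  run <- function(f) {
    tryCatch({
      r <- f(values)
      if (!is.finite(r$p_value)) {
        list(stat = NA_real_, p = NA_real_,
             note = "degenerate sample (non-finite p)")
      } else {
        list(stat = r$statistic, p = r$p_value, note = NA_character_)
      }
    }, error = function(e) {
      list(stat = NA_real_, p = NA_real_, note = conditionMessage(e))
    })
  }
  res <- list(
    `D'Agostino-Pearson` = run(dagostino_pearson),
    `Shapiro-Wilk` = run(function(v) {
      r <- stats::shapiro.test(v)
      list(statistic = unname(r$statistic), p_value = r$p.value)
    }),
    `Anderson-Darling` = run(function(v) {
      r <- nortest::ad.test(v)
      list(statistic = unname(r$statistic), p_value = r$p.value)
    }),
    `Kolmogorov-Smirnov` = run(function(v) {
      r <- nortest::lillie.test(v)
      list(statistic = unname(r$statistic), p_value = r$p.value)
    })
  )
  data.frame(
    test = names(res),
    statistic = vapply(res, function(r) as.numeric(r$stat), numeric(1)),
    p_value = vapply(res, function(r) as.numeric(r$p), numeric(1)),
    note = vapply(res, function(r) r$note, character(1)),
    row.names = NULL
  )
}

#' Simple linear regression correlation
#'
#' Ordinary least-squares fit of `y ~ x` reporting slope, intercept, R^2
#' and the two-sided p-value for a zero slope.
#'
#' @param x,y numeric vectors of equal length (n >= 3, `x` non-constant).
#' @return list of class `correlation_result`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
linreg_correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("correlation requires at least 3 paired values")
  if (stats::sd(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n = length(x)
  ), class = "correlation_result")
}

#' SuperPlot-style replicate aggregation
#'
#' Emits the pooled per-observation table together with per-replicate
#' means per group, the two layers of a SuperPlot: every data point
#' labelled by biological replicate, plus the replicate averages whose
#' spread conveys reproducibility.  The weighted mean of replicate means
#' (weights = replicate n) equals the pooled group mean.
#'
#' @param values numeric observations.
#' @param replicate replicate label per observation.
#' @param group group label per observation.
#' @return list of class `superplot_table`: `points` (value, replicate,
#'   group) and `replicate_means` (group, replicate, n, mean).
#' @export
superplot_table <- function(values, replicate, group) {
  n <- length(values)
  if (length(replicate) != n || length(group) != n) {
    stop("values, replicate and group must have equal length")
  }
  if (any(is.na(replicate)) || any(is.na(group))) {
    stop("unknown (missing) replicate or group label")
  }
  points <- data.frame(value = values,
                       replicate = as.character(replicate),
                       group = as.character(group))
  agg <- stats::aggregate(value ~ group + replicate, data = points,
                          FUN = mean)
  cnt <- stats::aggregate(value ~ group + replicate, data = points,
                          FUN = length)
  means <- data.frame(group = agg$group, replicate = agg$replicate,
                      n = cnt$value, mean = agg$value)
  means <- means[order(means$group, means$replicate), ]
  rownames(means) <- NULL
  structure(list(points = points, replicate_means = means),
            class = "superplot_table")
}
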