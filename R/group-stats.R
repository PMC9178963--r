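# Group-comparison statistics implemented from first principles
# (midrank-based Kruskal-Wallis with tie correction, Dunn's post hoc
# z-tests, classical one-way ANOVA), plus the log-linear RMR model.

as_group_list <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least 2 groups", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  lapply(groups, as.numeric)
}

# Midranks and tie bookkeeping shared by kruskal_wallis and dunn_posthoc.
rank_setup <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  r <- rank(x)  # midranks
  tie_sizes <- table(x)
  list(n = length(x), g = g, r = r,
       tie_term = sum(tie_sizes^3 - tie_sizes),
       mean_ranks = tapply(r, g, mean)[names(groups)],
       sizes = vapply(groups, length, integer(1)))
}

#' Kruskal-Wallis rank-sum test
#'
#' Computes the Kruskal-Wallis H statistic on midranks with the standard
#' tie correction, and a p-value from the chi-square distribution with
#' k - 1 degrees of freedom. When every observation is identical the tie
#' correction denominator vanishes; the convention adopted is H = 0,
#' p = 1.
#'
#' @param groups a named list of numeric vectors (one per group).
#' @return An object of class `group_comparison`: a list with `method`,
#'   `statistic` (H), `df`, `p_value`, `groups` (sizes).
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  rs <- rank_setup(groups)
  n <- rs$n
  k <- length(groups)
  h_raw <- 12 / (n * (n + 1)) *
    sum(rs$sizes * (rs$mean_ranks - (n + 1) / 2)^2)
  correction <- 1 - rs$tie_term / (n^3 - n)
  if (correction <= 0) {
    h <- 0; p <- 1
  } else {
    h <- h_raw / correction
    p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  }
  structure(list(method = "Kruskal-Wallis", statistic = h, df = k - 1,
                 p_value = p, groups = rs$sizes),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g (k = %d groups)\n",
              x$method, x$statistic, paste(x$df, collapse = ", "),
              x$p_value, length(x$groups)))
  invisible(x)
}

#' Dunn's post hoc multiple comparisons
#'
#' Pairwise z-tests on mean midranks following a Kruskal-Wallis test:
#' \deqn{z_{ij} = \frac{\bar r_i - \bar r_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum (t^3 - t)}{12(N-1)}\right)
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' with two-sided p-values from the standard normal and optional
#' family-wise adjustment.
#'
#' @param groups a named list of numeric vectors.
#' @param adjustment `"none"` (default), `"bonferroni"` or `"holm"`.
#' @return Data frame with one row per pair: `group_i`, `group_j`, `z`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjustment = c("none", "bonferroni",
                                                "holm")) {
  adjustment <- match.arg(adjustment)
  groups <- as_group_list(groups)
  rs <- rank_setup(groups)
  n <- rs$n
  k <- length(groups)
  var_term <- n * (n + 1) / 12 - rs$tie_term / (12 * (n - 1))
  pairs <- utils::combn(names(groups), 2)
  rows <- apply(pairs, 2, function(p) {
    i <- p[1]; j <- p[2]
    se <- sqrt(var_term * (1 / rs$sizes[[i]] + 1 / rs$sizes[[j]]))
    z <- if (se > 0) (rs$mean_ranks[[i]] - rs$mean_ranks[[j]]) / se else 0
    data.frame(group_i = i, group_j = j, z = z,
               p_unadjusted = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjustment == "none") out$p_unadjusted
    else stats::p.adjust(out$p_unadjusted, method = adjustment)
  rownames(out) <- NULL
  out
}

#' Classical one-way ANOVA
#'
#' Between/within sum-of-squares decomposition with an F statistic on
#' (k - 1, N - k) degrees of freedom. Degenerate inputs follow explicit
#' conventions: zero within-group variance with equal group means gives
#' F = 0 (p = 1); zero within-group variance with unequal means gives an
#' infinite F (p = 0), flagged via the statistic itself.
#'
#' @param groups a named list of numeric vectors; total n must exceed the
#'   number of groups.
#' @return An object of class `group_comparison` with `statistic` (F),
#'   `df` (numerator, denominator), `p_value`, `ss` (between, within,
#'   total).
#' @export
one_way_anova <- function(groups) {
  groups <- as_group_list(groups)
  k <- length(groups)
  n_i <- vapply(groups, length, integer(1))
  n <- sum(n_i)
  if (n <= k) stop("total n must exceed the number of groups", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  grand <- mean(x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(seq_len(k),
                    function(i) sum((groups[[i]] - means[i])^2), numeric(1)))
  df1 <- k - 1
  df2 <- n - k
  if (ssw <= .Machine$double.eps * n) {
    if (ssb <= .Machine$double.eps * n) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(list(method = "One-way ANOVA", statistic = f, df = c(df1, df2),
                 p_value = p, groups = n_i,
                 ss = c(between = ssb, within = ssw, total = ssb + ssw)),
            class = "group_comparison")
}

#' Log-linear model of routine metabolic rate on temperature
#'
#' Fits `ln(RMR) = slope * temperature + intercept[watershed] + error` by
#' ordinary least squares: a common temperature slope with one intercept
#' per watershed. This is a fixed-effects approximation of a mixed model
#' with random treatment and fish intercepts; at the design scale used
#' here the slope and watershed offsets are recovered without the
#' random-effects machinery. Rows with non-positive RMR are dropped with a
#' warning.
#'
#' @param rows data frame with columns `rmr` (> 0), `temp_c`, `watershed`;
#'   at least 10 rows.
#' @return An object of class `rmr_model_fit`: a list with `slope_per_c`,
#'   `intercepts` (named per watershed), `residual_sd`, `n`, and the
#'   underlying `lm` fit.
#' @export
fit_rmr_model <- function(rows) {
  req <- c("rmr", "temp_c", "watershed")
  if (!all(req %in% names(rows))) {
    stop("rows must contain columns rmr, temp_c, watershed", call. = FALSE)
  }
  bad <- !is.finite(rows$rmr) | rows$rmr <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d row(s) with non-positive RMR", sum(bad)),
            call. = FALSE)
    rows <- rows[!bad, , drop = FALSE]
  }
  if (nrow(rows) < 10L) {
    stop("RMR model needs >= 10 rows", call. = FALSE)
  }
  d <- data.frame(lrmr = log(rows$rmr), temp_c = rows$temp_c,
                  watershed = factor(rows$watershed))
  if (nlevels(d$watershed) >= 2L) {
    fit <- stats::lm(lrmr ~ 0 + watershed + temp_c, data = d)
    cf <- stats::coef(fit)
    ints <- cf[grep("^watershed", names(cf))]
    names(ints) <- sub("^watershed", "", names(ints))
  } else {
    fit <- stats::lm(lrmr ~ temp_c, data = d)
    cf <- stats::coef(fit)
    ints <- stats::setNames(cf[["(Intercept)"]], levels(d$watershed))
  }
  structure(list(slope_per_c = unname(cf[["temp_c"]]),
                 intercepts = ints,
                 residual_sd = stats::sigma(fit),
                 n = nrow(d), fit = fit),
            class = "rmr_model_fit")
}

#' @export
print.rmr_model_fit <- function(x, ...) {
  cat(sprintf(
    "ln(RMR) ~ %.4f * temp + watershed intercept (n = %d, resid sd %.3f)\n",
    x$slope_per_c, x$n, x$residual_sd))
  print(round(x$intercepts, 4))
  invisible(x)
}

#' Compare a trait across treatments or watersheds
#'
#' Convenience wrapper running [kruskal_wallis()] and, when significant at
#' `alpha`, [dunn_posthoc()] on one trait column split by a grouping
#' column.
#'
#' @param df data frame of per-fish values.
#' @param value name of the trait column.
#' @param by name of the grouping column.
#' @param adjustment Dunn adjustment method.
#' @param alpha significance level gating the post hoc test (default
#'   0.05).
#' @return A list with `test` (a `group_comparison`) and `pairwise` (a
#'   Dunn table, or `NULL` when the omnibus test is not significant).
#' @export
compare_groups <- function(df, value, by, adjustment = "none",
                           alpha = 0.05) {
  groups <- split(df[[value]], df[[by]])
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  kw <- kruskal_wallis(groups)
  pw <- if (kw$p_value < alpha) dunn_posthoc(groups, adjustment) else NULL
  list(test = kw, pairwise = pw)
}
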