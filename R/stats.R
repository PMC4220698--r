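## stats: the study's statistical procedures. The two-sample t and K-S
## statistics are computed in closed form here (and cross-checked against
## stats::t.test / stats::ks.test in the test suite); the Hartley F_max
## homoscedasticity test uses the embedded critical-value table with a
## seeded Monte-Carlo fallback.

#' Two-sample t test (pooled Student or Welch)
#'
#' @param a,b numeric samples, each with at least 2 values.
#' @param variant `"pooled"` (classical Student, default) or `"welch"`.
#' @return list: `t`, `df`, `p` (two-tailed), `variant`, group means.
#' @export
ttest_two_sample <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  check_that(is.numeric(a) && length(a) >= 2, "`a` needs at least 2 values")
  check_that(is.numeric(b) && length(b) >= 2, "`b` needs at least 2 values")
  n1 <- length(a); n2 <- length(b)
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    se <- sqrt(se2)
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       variant = variant, mean_a = m1, mean_b = m2)
}

## Asymptotic Kolmogorov survival function Q(lambda) = P(K > lambda),
## evaluated to machine precision by whichever theta-series converges
## faster at the given argument.
kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  if (lambda < 1) {
    ## rapidly converging form for small arguments
    s <- 0
    for (k in 1:20) {
      s <- s + exp(-(2 * k - 1)^2 * pi^2 / (8 * lambda^2))
    }
    return(1 - sqrt(2 * pi) / lambda * s)
  }
  s <- 0
  for (k in 1:100) {
    term <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    s <- s + term
    if (abs(term) < 1e-17) break
  }
  min(max(2 * s, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test on cumulative distributions
#'
#' `D` is the supremum distance between the two empirical CDFs; the
#' two-sided p value is the asymptotic Kolmogorov approximation at
#' `sqrt(n1 n2 / (n1 + n2)) * D`.
#'
#' @param a,b non-empty numeric samples.
#' @return list: `D`, `p`, sample sizes.
#' @export
ks_two_sample <- function(a, b) {
  check_that(is.numeric(a) && length(a) >= 1, "`a` must be non-empty")
  check_that(is.numeric(b) && length(b) >= 1, "`b` must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  ord <- order(pooled)
  z <- cumsum(ifelse(ord <= n1, 1 / n1, -1 / n2))
  srt <- pooled[ord]
  keep <- c(diff(srt) != 0, TRUE)   # at ties, only the group end counts
  D <- max(abs(z[keep]))
  lambda <- sqrt(n1 * n2 / (n1 + n2)) * D
  list(D = D, p = kolmogorov_q(lambda), n1 = n1, n2 = n2)
}

#' Hartley F_max homoscedasticity test
#'
#' Computes the ratio of the largest to the smallest subgroup variance
#' within a group (e.g. the per-mouse variances of one genotype) and
#' compares it with the critical F_max at level `alpha` for `k`
#' subgroups and `df = n - 1` degrees of freedom. Critical values come
#' from the embedded published table (k = 2..12, df = 2..60, alpha =
#' 0.05, interpolated in 1/df between tabulated rows); outside the table
#' a seeded Monte-Carlo estimate under the normal equal-variance null is
#' used. The null (equal variances) is accepted iff
#' `F_max <= critical_F_max`.
#'
#' @param values numeric observations.
#' @param subgroup parallel vector of subgroup labels (e.g. mouse ids);
#'   at least 2 subgroups with at least 2 observations each.
#' @param alpha significance level (default 0.05).
#' @param n_mc Monte-Carlo replicates for the fallback (default 1e5).
#' @param mc_seed seed for the fallback simulation.
#' @return list of class `fmax_result`: `f_max`, `critical_f_max`,
#'   `alpha`, `k`, `n` (subgroup sizes), `df`, `equal_variances`
#'   (decision), `method` (`"table"` or `"monte-carlo"`).
#' @export
fmax_test <- function(values, subgroup, alpha = 0.05, n_mc = 1e5, mc_seed = 1L) {
  check_that(is.numeric(values) && length(values) == length(subgroup),
             "`values` and `subgroup` must be parallel vectors")
  check_number(alpha, "alpha", positive = TRUE)
  check_that(alpha < 1, "`alpha` must be < 1")
  groups <- split(values, subgroup)
  k <- length(groups)
  check_that(k >= 2, "need at least 2 subgroups")
  sizes <- vapply(groups, length, integer(1))
  check_that(all(sizes >= 2), "every subgroup needs at least 2 observations")
  vars <- vapply(groups, stats::var, numeric(1))
  check_that(all(vars > 0), "a subgroup has zero variance: F_max undefined",
             class = "synmorph_degenerate_variance")
  f_max <- max(vars) / min(vars)
  df <- round(mean(sizes)) - 1L
  crit <- hartley_critical(k, df, alpha)
  method <- "table"
  if (is.na(crit)) {
    crit <- hartley_critical_mc(k, df, alpha, n_rep = n_mc, seed = mc_seed)
    method <- "monte-carlo"
  }
  out <- list(f_max = f_max, critical_f_max = crit, alpha = alpha,
              k = k, n = sizes, df = df,
              equal_variances = f_max <= crit, method = method)
  class(out) <- "fmax_result"
  out
}

#' @export
print.fmax_result <- function(x, ...) {
  cat(sprintf("<fmax_result> F_max = %.3f vs critical %.3f (k = %d, df = %d, alpha = %g, %s): variances %s\n",
              x$f_max, x$critical_f_max, x$k, x$df, x$alpha, x$method,
              if (x$equal_variances) "equal (null accepted)" else "unequal (null rejected)"))
  invisible(x)
}

#' Coefficient of variation, study definition
#'
#' The study defines its CV as the square root of the ratio of SD to
#' mean; that non-standard (and dimensionally odd) form is the default
#' here, with the conventional `SD/mean` behind `variant =
#' "conventional"`. The variant used is always part of the output.
#'
#' @param x numeric sample (ignored when `sd` and `mean` are supplied).
#' @param sd,mean optionally supply the summary statistics directly.
#' @param variant `"paper"` (`sqrt(SD/mean)`, default) or
#'   `"conventional"` (`SD/mean`).
#' @return list: `cv`, `variant`, `sd`, `mean`.
#' @export
cv_paper <- function(x = NULL, sd = NULL, mean = NULL,
                     variant = c("paper", "conventional")) {
  variant <- match.arg(variant)
  if (is.null(sd) || is.null(mean)) {
    check_that(is.numeric(x) && length(x) >= 2,
               "`x` needs at least 2 values when sd/mean are not given")
    sd <- stats::sd(x)
    mean <- base::mean(x)
  }
  check_that(mean > 0, "`mean` must be positive for this CV definition")
  check_that(sd >= 0, "`sd` must be non-negative")
  cv <- if (variant == "paper") sqrt(sd / mean) else sd / mean
  list(cv = cv, variant = variant, sd = sd, mean = mean)
}

#' Contact-geometry comparison between two genotypes
#'
#' Treats each synaptic contact as a disc whose diameter is the mean AZ
#' length (area `pi (L/2)^2`) and the synaptic cleft as a cylinder of
#' that base area and height equal to the mean cleft width. Reports the
#' percent difference of the second group relative to the first for AZ
#' length, contact area, cleft width and cleft volume.
#'
#' @param wt,ko each `c(az_length, cleft_width)` in nm (reference group
#'   first).
#' @return list of class `geometry_summary`: per-group `area` (nm^2) and
#'   `volume` (nm^3), and `pct_increase` (named: length, area, width,
#'   volume).
#' @export
geometry_comparison <- function(wt, ko) {
  chk <- function(v, name) {
    check_that(is.numeric(v) && length(v) == 2L && all(v > 0),
               sprintf("`%s` must be positive c(az_length, cleft_width)", name))
  }
  chk(wt, "wt"); chk(ko, "ko")
  disc <- function(L) pi * (L / 2)^2
  a_wt <- disc(wt[1]); a_ko <- disc(ko[1])
  v_wt <- a_wt * wt[2]; v_ko <- a_ko * ko[2]
  pct <- function(x0, x1) 100 * (x1 - x0) / x0
  out <- list(wt = list(az_length = wt[1], cleft_width = wt[2],
                        area = a_wt, volume = v_wt),
              ko = list(az_length = ko[1], cleft_width = ko[2],
                        area = a_ko, volume = v_ko),
              pct_increase = c(length = pct(wt[1], ko[1]),
                               area = pct(a_wt, a_ko),
                               width = pct(wt[2], ko[2]),
                               volume = pct(v_wt, v_ko)))
  class(out) <- "geometry_summary"
  out
}

#' @export
print.geometry_summary <- function(x, ...) {
  p <- x$pct_increase
  cat(sprintf("<geometry_summary> AZ length %+.1f%%, contact area %+.1f%%, cleft width %+.1f%%, cleft volume %+.1f%%\n",
              p["length"], p["area"], p["width"], p["volume"]))
  invisible(x)
}
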