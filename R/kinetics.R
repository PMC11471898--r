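## Per-treatment rate estimation and the group-comparison statistics used
## alongside it. Nitrification rate is defined as the NH4+-N disappearance
## slope (sign-flipped): the microcosms measure KCl-extractable ammonium,
## and yields are expressed per NH4+-N oxidized, so ammonium depletion is
## the natural substrate axis. Zero-order (linear) kinetics are assumed
## over the 3-day incubation.

#' Ordinary least-squares rate from a time series
#'
#' Fits `value ~ time` by OLS over all supplied points (replicates pooled)
#' and reports the slope converted to per-day units with its standard
#' error. With exactly two points the fit is saturated and the SE is 0.
#'
#' @param times_h Observation times in hours (>= 2 distinct values).
#' @param values Analyte values (canonical per-gram units).
#' @return List with `slope_per_day`, `se_per_day`, `slope_per_hour`,
#'   `n_points`, and the `fit` (an `lm` object).
#' @examples
#' fit_linear_rate(c(0, 24, 48, 72), c(10, 9, 8.2, 6.8))$slope_per_day  # -1.04
#' @export
fit_linear_rate <- function(times_h, values) {
  stopifnot(length(times_h) == length(values))
  if (length(unique(times_h)) < 2)
    stop("need >= 2 distinct timepoints to fit a rate")
  fit <- stats::lm(values ~ times_h)
  slope_h <- unname(stats::coef(fit)[2])
  ## slope SE from residual variance directly (avoids summary.lm's
  ## perfect-fit warning on zero-noise data); 0 for a saturated 2-point fit
  n <- length(times_h)
  se_h <- if (n > 2) {
    sxx <- sum((times_h - mean(times_h))^2)
    sqrt(sum(stats::residuals(fit)^2) / (n - 2) / sxx)
  } else 0
  list(slope_per_day = slope_h * 24, se_per_day = se_h * 24,
       slope_per_hour = slope_h, n_points = length(times_h), fit = fit)
}

#' Summarise one treatment: nitrification rate and cumulative N2O
#'
#' The nitrification rate is minus the pooled OLS slope of the NH4+-N
#' series (all replicate points in one fit, since destructive sampling
#' leaves replicates unpaired across timepoints); negative estimates are
#' clamped to 0 with the raw value retained. Cumulative N2O is the mean
#' over replicates of (final - baseline) N2O mass; its SE is the standard
#' error of that mean difference across replicates, when computable.
#'
#' @param table A `measurement_table` containing `NH4_N` and `N2O_mass`
#'   records for the treatment (run [add_n2o_mass()] first if only
#'   mixing ratios were measured).
#' @param treatment Treatment name.
#' @param per_replicate If `TRUE`, fit one slope per replicate and average
#'   (the pooled fit is the default; see Details).
#' @return A `treatment_summary` list: `treatment`, `nitrification_rate`
#'   (ug N g^-1 d^-1, >= 0), `rate_se`, `rate_raw` (pre-clamp),
#'   `n2o_cumulative` (ng N2O-N g^-1), `n2o_se`, `n_replicates`,
#'   `low_support` flag.
#' @export
summarize_treatment <- function(table, treatment, per_replicate = FALSE) {
  nh4 <- analyte_series(table, treatment, "NH4_N")
  n2o <- analyte_series(table, treatment, "N2O_mass")
  if (nrow(nh4) == 0) stop(sprintf("treatment '%s': missing analyte NH4_N", treatment))
  if (nrow(n2o) == 0)
    stop(sprintf("treatment '%s': missing analyte N2O_mass (convert N2O_ppb with add_n2o_mass())",
                 treatment))

  if (per_replicate) {
    fits <- lapply(split(nh4, nh4$replicate),
                   function(d) fit_linear_rate(d$time_h, d$value))
    slopes <- vapply(fits, `[[`, numeric(1), "slope_per_day")
    slope <- mean(slopes)
    se <- if (length(slopes) > 1) stats::sd(slopes) / sqrt(length(slopes)) else 0
  } else {
    f <- fit_linear_rate(nh4$time_h, nh4$value)
    slope <- f$slope_per_day
    se <- f$se_per_day
  }
  raw_rate <- -slope

  ## cumulative N2O per replicate: final minus baseline mass
  t_final <- max(n2o$time_h)
  base <- n2o[n2o$time_h == 0, ]
  fin <- n2o[n2o$time_h == t_final, ]
  if (nrow(base) == 0)
    stop(sprintf("treatment '%s': no t = 0 N2O record; baseline subtraction impossible", treatment))
  base_mean <- mean(base$value)
  per_rep <- fin$value - base_mean
  n2o_cum <- mean(per_rep)
  n2o_se <- if (length(per_rep) > 1) stats::sd(per_rep) / sqrt(length(per_rep)) else 0

  n_rep <- length(unique(nh4$replicate))
  structure(list(
    treatment = treatment,
    nitrification_rate = max(raw_rate, 0),
    rate_raw = raw_rate,
    rate_se = se,
    n2o_cumulative = n2o_cum,
    n2o_se = n2o_se,
    n_replicates = n_rep,
    low_support = n_rep < 2 || length(unique(nh4$time_h)) <= 2
  ), class = "treatment_summary")
}

#' Summarise every treatment in a design
#'
#' @inheritParams summarize_treatment
#' @param design A [microcosm_design()]; its scheme fixes treatment order.
#' @return Named list of `treatment_summary`, in scheme order.
#' @export
summarize_all_treatments <- function(table, design, per_replicate = FALSE) {
  trts <- names(design$inhibitor_scheme)
  out <- lapply(trts, function(t) summarize_treatment(table, t, per_replicate))
  names(out) <- trts
  out
}

#' One-way ANOVA across groups
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test), as used
#' to compare treatments or sampling months.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return List with `f`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(values) == 0)
    stop("all values identical: F undefined (zero between- and within-group variance)")
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  list(f = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df_between = tab[["Df"]][1], df_within = tab[["Df"]][2])
}

#' Fisher's least significant difference test
#'
#' Unadjusted pairwise t tests sharing the pooled within-group mean square
#' from the one-way ANOVA, plus the LSD threshold at `alpha` for each pair.
#'
#' @param groups List of numeric vectors (named, optionally).
#' @param alpha Significance level for the LSD threshold (default 0.05).
#' @return Data frame with one row per pair: `group1`, `group2`,
#'   `mean_diff`, `t`, `p`, `lsd`, `significant`.
#' @export
fisher_lsd <- function(groups, alpha = 0.05) {
  an <- anova_oneway(groups)  # validates inputs, shares MSW via recompute below
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::aov(values ~ g)
  msw <- summary(fit)[[1]][["Mean Sq"]][2]
  df_w <- an$df_within
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  means <- vapply(groups, mean, numeric(1))
  ns <- lengths(groups)
  pairs <- utils::combn(seq_along(groups), 2)
  res <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sed <- sqrt(msw * (1 / ns[i] + 1 / ns[j]))
    tval <- unname((means[i] - means[j]) / sed)
    p <- 2 * stats::pt(-abs(tval), df_w)
    lsd <- stats::qt(1 - alpha / 2, df_w) * sed
    c(diff = unname(means[i] - means[j]), t = tval, p = p, lsd = lsd)
  }, c(diff = 0, t = 0, p = 0, lsd = 0))
  data.frame(
    group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
    mean_diff = res["diff", ], t = res["t", ], p = res["p", ],
    lsd = res["lsd", ], significant = res["p", ] < alpha,
    row.names = NULL
  )
}
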