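# Closed-form association statistics for the cohort analyses.
#
# The study's mixed-effects adjustment reduces, with one measurement per
# animal, to ordinary least squares with survival week as a fixed covariate;
# r-squared is reported as the squared Pearson correlation between the
# week-residualized predictor and outcome (the semi-partial definition the
# generator is calibrated under).

#' Two-group one-way ANOVA F test
#'
#' Equivalent to the squared pooled two-sample t test.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `F`, `p`, `df` (c(1, n-2)), `mean_diff`, `degenerate`
#'   (TRUE when pooled variance is zero with unequal means).
#' @export
two_group_f_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(c(a, b))))
  n1 <- length(a); n2 <- length(b)
  df2 <- n1 + n2 - 2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  ssb <- n1 * n2 / (n1 + n2) * (mean(a) - mean(b))^2
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, p = 1, df = c(1, df2), mean_diff = 0,
                              degenerate = FALSE))
    return(list(F = Inf, p = 0, df = c(1, df2),
                mean_diff = mean(a) - mean(b), degenerate = TRUE))
  }
  Fval <- ssb / (ssw / df2)
  list(F = Fval, p = pf(Fval, 1, df2, lower.tail = FALSE), df = c(1, df2),
       mean_diff = mean(a) - mean(b), degenerate = FALSE)
}

#' Paired epoch-vs-baseline comparison for one physiology variable
#'
#' Paired t test of the per-animal difference between `epoch` and baseline in
#' the H-I group, Bonferroni-corrected for the three non-baseline epochs.
#'
#' @param cohort a `glia_cohort`.
#' @param variable physiology variable name (e.g. `"glucose"`).
#' @param epoch one of `"hypoxia"`, `"hypoxia_ischemia"`, `"recovery"`.
#' @return list with `mean_diff`, `p` (Bonferroni-adjusted), `p_raw`, `n`.
#' @export
epoch_vs_baseline <- function(cohort, variable,
                              epoch = c("hypoxia", "hypoxia_ischemia", "recovery")) {
  epoch <- match.arg(epoch)
  ep <- cohort$epochs[cohort$epochs$group == "HI", ]
  if (!variable %in% names(ep)) stopf("unknown variable '%s'", variable)
  base <- ep[ep$epoch == "baseline", c("animal_id", variable)]
  at <- ep[ep$epoch == epoch, c("animal_id", variable)]
  m <- merge(base, at, by = "animal_id", suffixes = c("_base", "_epoch"))
  x <- m[[paste0(variable, "_base")]]
  y <- m[[paste0(variable, "_epoch")]]
  if (nrow(m) < 2 || anyNA(x) || anyNA(y))
    stopf("paired %s values unavailable at %s", variable, epoch)
  d <- y - x
  if (sd(d) == 0) {
    p_raw <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- stats::t.test(d)
    p_raw <- tt$p.value
  }
  list(mean_diff = mean(d), p = min(1, 3 * p_raw), p_raw = p_raw, n = nrow(m))
}

#' Survival-week-adjusted linear association
#'
#' Fits `y ~ x + week` by least squares; slope, SE, t and p are for the
#' predictor term. `r2` is the squared Pearson correlation between the
#' week-residualized x and week-residualized y. When week is constant the
#' fit reduces exactly to simple linear regression.
#'
#' @param x predictor sample.
#' @param y outcome sample.
#' @param week survival-week covariate, aligned with `x` and `y`.
#' @param predictor,outcome names recorded in the result.
#' @return list of class `association_result`: `predictor`, `outcome`,
#'   `slope`, `se`, `t`, `p`, `r2`, `n`, `adjusted_for`.
#' @export
adjusted_linear_assoc <- function(x, y, week, predictor = "x", outcome = "y") {
  stopifnot(length(x) == length(y), length(x) == length(week))
  keep <- complete.cases(x, y, week)
  x <- x[keep]; y <- y[keep]; week <- week[keep]
  n <- length(x)
  if (n < 4) stopf("insufficient n (%d) for a week-adjusted association", n)
  if (var(x) == 0) stopf("constant predictor")
  const_week <- var(week) == 0
  if (!const_week && abs(cor(x, week)) > 0.99)
    stopf("predictor nearly collinear with survival week")
  fit <- if (const_week) lm(y ~ x) else lm(y ~ x + week)
  sm <- summary(fit)$coefficients["x", ]
  rx <- if (const_week) x - mean(x) else resid(lm(x ~ week))
  ry <- if (const_week) y - mean(y) else resid(lm(y ~ week))
  structure(list(predictor = predictor, outcome = outcome,
                 slope = unname(sm["Estimate"]), se = unname(sm["Std. Error"]),
                 t = unname(sm["t value"]), p = unname(sm["Pr(>|t|)"]),
                 r2 = cor(rx, ry)^2, n = n,
                 adjusted_for = if (const_week) character() else "survival_week"),
            class = "association_result")
}

#' Week-adjusted association profile of all predictors against both markers
#'
#' One association per predictor (cephalic BP, CaO2, glucose, lactate at the
#' hypoxia-ischemia epoch) and outcome (GFAP, Iba1 area fraction) over the
#' H-I animals, each adjusted for survival week, with within-outcome ranking
#' by r-squared.
#'
#' @param cohort a `glia_cohort`.
#' @return data frame with one row per predictor-outcome pair: `predictor`,
#'   `outcome`, `slope`, `se`, `t`, `p`, `r2`, `n`, `rank` (1 = strongest
#'   within its outcome).
#' @export
multi_predictor_profile <- function(cohort) {
  hi_ep <- cohort$epochs[cohort$epochs$epoch == "hypoxia_ischemia", ]
  an <- cohort$animals[cohort$animals$group == "HI", ]
  m <- merge(an, hi_ep[c("animal_id", "BP", "CaO2", "glucose", "lactate")],
             by = "animal_id")
  if (nrow(m) < 4) stopf("insufficient n (%d) for the association profile", nrow(m))
  rows <- list()
  for (out in c("GFAP", "Iba1")) {
    yv <- if (out == "GFAP") m$gfap_fraction else m$iba1_fraction
    for (pv in c("BP", "CaO2", "glucose", "lactate")) {
      a <- adjusted_linear_assoc(m[[pv]], yv, m$survival_week,
                                 predictor = pv, outcome = out)
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = pv, outcome = out, slope = a$slope, se = a$se, t = a$t,
        p = a$p, r2 = a$r2, n = a$n, stringsAsFactors = FALSE)
    }
  }
  prof <- do.call(rbind, rows)
  prof$rank <- stats::ave(-prof$r2, prof$outcome, FUN = rank)
  prof
}

#' @export
print.association_result <- function(x, ...) {
  adj <- if (length(x$adjusted_for)) paste(x$adjusted_for, collapse = ", ")
         else "none"
  cat(sprintf("%s ~ %s: slope %.4g (se %.3g), t = %.2f, p = %.3g, r2 = %.3f, n = %d (adjusted for %s)\n",
              x$outcome, x$predictor, x$slope, x$se, x$t, x$p, x$r2, x$n, adj))
  invisible(x)
}
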