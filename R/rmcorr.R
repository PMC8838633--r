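# Repeated-measures correlation: the common within-participant slope
# association between two repeatedly measured variables, estimated by ANCOVA
# with participant as a factor and the covariate sharing one slope.

#' Repeated-measures correlation
#'
#' Fits the ANCOVA `y ~ participant + x` (participant-specific intercepts,
#' one common slope) and reports
#' `r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_error))`, where `SS_x` is the
#' sequential sum of squares attributable to the covariate after the
#' participant factor. Degrees of freedom are `n_obs - n_participants - 1`
#' (equal to `N(k-1) - 1` for N participants with k points each); the p-value
#' is the F test of the covariate and the 95% CI uses the Fisher z transform
#' with the repeated-measures df.
#'
#' Participants with fewer than two points or a constant covariate carry no
#' within-person information and are excluded with a warning.
#'
#' @param records data.frame of trial records.
#' @param x,y Column names of the covariate and response (default CSA, JVA).
#' @param participant Column naming the participant id.
#' @return Object of class `chi_rmcorr`: `r_rm`, `ci_low`, `ci_high`, `p`,
#'   `common_slope`, `df`, `n_participants`, `n_obs`.
#' @export
rmcorr <- function(records, x = "csa", y = "jva", participant = "participant") {
  d <- data.frame(p = factor(records[[participant]]),
                  x = records[[x]], y = records[[y]])
  d <- d[stats::complete.cases(d), ]
  counts <- table(d$p)
  xvar <- tapply(d$x, d$p, function(v) stats::var(v) > 0)
  bad <- names(counts)[counts < 2 | !xvar[names(counts)]]
  if (length(bad) > 0) {
    warning("excluding participants with < 2 points or constant x: ",
            paste(bad, collapse = ", "))
    d <- d[!d$p %in% bad, ]
    d$p <- droplevels(d$p)
  }
  if (nlevels(d$p) < 2) stop("need >= 2 participants with >= 2 points each")
  m0 <- stats::lm(y ~ p, data = d)
  m1 <- stats::lm(y ~ p + x, data = d)
  rss0 <- sum(stats::resid(m0)^2)
  rss1 <- sum(stats::resid(m1)^2)
  ss_x <- rss0 - rss1
  n <- nrow(d)
  df <- n - nlevels(d$p) - 1L
  slope <- unname(stats::coef(m1)["x"])
  r_rm <- sign(slope) * sqrt(ss_x / (ss_x + rss1))
  f <- ss_x / (rss1 / df)
  p_val <- stats::pf(f, 1, df, lower.tail = FALSE)
  se_z <- 1 / sqrt(df - 1)
  ci <- tanh(atanh(r_rm) + c(-1, 1) * stats::qnorm(0.975) * se_z)
  structure(list(r_rm = r_rm, ci_low = ci[1], ci_high = ci[2], p = p_val,
                 common_slope = slope, df = df,
                 n_participants = nlevels(d$p), n_obs = n),
            class = "chi_rmcorr")
}

#' @export
print.chi_rmcorr <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures correlation\n  r_rm = %.3f (95%% CI %.3f, %.3f), p = %.4g, df = %d\n  common slope = %.4f per unit x (%d participants, %d points)\n",
    x$r_rm, x$ci_low, x$ci_high, x$p, x$df, x$common_slope,
    x$n_participants, x$n_obs))
  invisible(x)
}
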