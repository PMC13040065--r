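#' Fit a fractional-polynomial mean curve
#'
#' Least-squares fit of `y = b0 + b1 * GA^p1 + b2 * GA^p2` over all ordered
#' power pairs from the candidate set (power 0 is log GA; a repeated power p
#' uses GA^p and GA^p * log GA), selecting the pair with minimal residual sum
#' of squares.
#'
#' @param ga gestational ages in weeks.
#' @param y response values.
#' @param candidate_powers candidate power set; the conventional degree-2
#'   fractional-polynomial set by default.
#' @param weights optional case weights.
#' @param powers optional fixed power pair, bypassing selection.
#' @return list with `powers`, `mean_coeffs` (intercept, b1, b2), `rss` and
#'   the coefficient standard errors `se`.
#' @export
fit_fp_mean <- function(ga, y,
                        candidate_powers = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3),
                        weights = NULL, powers = NULL) {
  abort_if(length(ga) != length(y), "ga and y lengths differ")
  abort_if(length(ga) < 10, "insufficient data: need at least 10 points")
  abort_if(any(ga <= 0), "gestational ages must be positive")
  w <- if (is.null(weights)) rep(1, length(ga)) else weights
  if (!is.null(powers)) {
    pairs <- list(sort(powers))
  } else {
    pairs <- list()
    ps <- sort(candidate_powers)
    for (i in seq_along(ps)) for (j in i:length(ps))
      pairs[[length(pairs) + 1]] <- c(ps[i], ps[j])
  }
  best <- NULL
  for (pw in pairs) {
    X <- cbind(1, fp_design(ga, pw))
    fit <- lm.fit(X * sqrt(w), y * sqrt(w))
    if (fit$rank < 3) next
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(powers = pw, mean_coeffs = unname(fit$coefficients),
                   rss = rss)
  }
  abort_if(is.null(best),
           "rank-deficient design for every candidate power pair")
  # standard errors at the selected pair
  X <- cbind(1, fp_design(ga, best$powers))
  xtx <- crossprod(X * sqrt(w))
  sigma2 <- best$rss / (length(y) - 3)
  best$se <- sqrt(diag(solve(xtx)) * sigma2)
  best
}

#' Fit the log-linear SD curve
#'
#' Models log SD as a linear function of gestational age.  Given residuals
#' from a mean fit, per-week bin means of the half-normal-corrected absolute
#' residuals (sqrt(pi/2) |r|, unbiased for the SD under Gaussian errors) are
#' computed first and the line is fitted to their logs, weighted by bin
#' counts.  Given exact SD values via `sd`, the line is fitted to log(sd)
#' directly.
#'
#' @param ga gestational ages in weeks.
#' @param residuals residuals from a fitted mean model.
#' @param sd exact SD values (alternative to `residuals`).
#' @return list with `sd_coeffs` (intercept, slope of log SD vs GA) and their
#'   standard errors `se`.
#' @export
fit_log_sd <- function(ga, residuals = NULL, sd = NULL) {
  abort_if(is.null(residuals) == is.null(sd),
           "supply exactly one of residuals or sd")
  if (!is.null(sd)) {
    abort_if(any(sd <= 0), "SD values must be positive")
    X <- cbind(1, ga)
    fit <- lm.fit(X, log(sd))
    sigma2 <- sum(fit$residuals^2) / max(length(sd) - 2, 1)
    return(list(sd_coeffs = unname(fit$coefficients),
                se = sqrt(diag(solve(crossprod(X))) * sigma2)))
  }
  abort_if(all(abs(residuals) < 1e-12), "all residuals zero: SD degenerate")
  bin <- floor(ga)
  corrected <- sqrt(pi / 2) * abs(residuals)
  agg_m <- tapply(corrected, bin, mean)
  agg_ga <- tapply(ga, bin, mean)
  agg_n <- tapply(ga, bin, length)
  ok <- agg_m > 0 & agg_n >= 2
  abort_if(sum(ok) < 2, "too few GA bins to fit the SD curve")
  fit <- lm(log(agg_m[ok]) ~ agg_ga[ok], weights = agg_n[ok])
  list(sd_coeffs = unname(coef(fit)),
       se = unname(summary(fit)$coefficients[, 2]))
}

#' Fit a full growth standard (mean and SD)
#'
#' Staged scheme: ordinary least-squares fractional-polynomial mean fit,
#' log-linear SD fit on its residuals, one weighted refit of the mean with
#' weights 1/SD(GA)^2 (keeping the selected powers), and one SD refit on the
#' new residuals.
#'
#' @param ga gestational ages in weeks.
#' @param y response values.
#' @param ga_domain model domain (no extrapolation outside it).
#' @param candidate_powers passed to [fit_fp_mean()].
#' @return an [fp_growth_model()], with the coefficient standard errors of
#'   the final fits attached as attributes `mean_se` and `sd_se`.
#' @export
fit_growth_model <- function(ga, y, ga_domain = c(18, 27),
                             candidate_powers = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)) {
  keep <- complete.cases(ga, y)
  ga <- ga[keep]; y <- y[keep]
  m1 <- fit_fp_mean(ga, y, candidate_powers)
  res1 <- y - drop(cbind(1, fp_design(ga, m1$powers)) %*% m1$mean_coeffs)
  if (all(abs(res1) < 1e-10)) {
    # noiseless data: the OLS fit is already exact; keep a tiny nominal SD
    sd_fit <- list(sd_coeffs = c(-Inf, 0), se = c(NA, NA))
    model <- fp_growth_model(m1$powers, m1$mean_coeffs,
                             sd_coeffs = c(log(.Machine$double.eps), 0),
                             ga_domain = ga_domain, n_fitted = length(y))
    attr(model, "mean_se") <- m1$se
    attr(model, "sd_se") <- c(NA_real_, NA_real_)
    return(model)
  }
  s1 <- fit_log_sd(ga, residuals = res1)
  w <- 1 / exp(2 * (s1$sd_coeffs[1] + s1$sd_coeffs[2] * ga))
  m2 <- fit_fp_mean(ga, y, weights = w, powers = m1$powers)
  res2 <- y - drop(cbind(1, fp_design(ga, m2$powers)) %*% m2$mean_coeffs)
  s2 <- fit_log_sd(ga, residuals = res2)
  model <- fp_growth_model(m2$powers, m2$mean_coeffs, s2$sd_coeffs,
                           ga_domain = ga_domain, n_fitted = length(y))
  attr(model, "mean_se") <- m2$se
  attr(model, "sd_se") <- s2$se
  model
}

#' Centiles and z-scores of a growth standard
#'
#' `predict_centile` returns mean(GA) + qnorm(p) * SD(GA); `zscore` returns
#' (y - mean(GA)) / SD(GA).  The two are exact inverses:
#' `predict_centile(model, ga, pnorm(zscore(model, ga, y)))` recovers `y`.
#'
#' @param model an [fp_growth_model()].
#' @param ga gestational ages within the model domain (no extrapolation).
#' @param p centile as a probability in (0, 1).
#' @param y observed values.
#' @return numeric vector of centile values / z-scores.
#' @export
predict_centile <- function(model, ga, p) {
  check_domain(model, ga)
  abort_if(any(p <= 0 | p >= 1), "centile probability must be in (0, 1)")
  predict_mean(model, ga) + qnorm(p) * predict_sd(model, ga)
}

#' @rdname predict_centile
#' @export
zscore <- function(model, ga, y) {
  check_domain(model, ga)
  (y - predict_mean(model, ga)) / predict_sd(model, ga)
}

#' Exclude gestational-age-specific outliers
#'
#' Single-pass filter: the mean and SD of the IDP are computed in integer
#' -week bins over all sites pooled, and rows farther than `k` bin-SDs from
#' the bin mean are removed.  Bins with fewer than 3 rows are skipped with a
#' warning (no exclusion there).
#'
#' @param table IDP data.frame with a `ga_weeks` column.
#' @param idp name of the IDP column to filter on.
#' @param k exclusion threshold in SD multiples (default 4).
#' @return list with `table` (retained rows) and `removed` (count).
#' @export
exclude_outliers <- function(table, idp, k = 4) {
  abort_if(!idp %in% names(table), paste("no column", idp))
  bin <- floor(table$ga_weeks)
  keep <- rep(TRUE, nrow(table))
  for (b in unique(bin)) {
    sel <- which(bin == b)
    if (length(sel) < 3) {
      warning(sprintf("GA bin %d has < 3 rows; no exclusion applied there", b))
      next
    }
    v <- table[[idp]][sel]
    m <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) next
    keep[sel[abs(v - m) > k * s]] <- FALSE
  }
  list(table = table[keep, , drop = FALSE], removed = sum(!keep))
}

#' Empirical versus smoothed centiles
#'
#' Per integer gestational week with at least `min_n` rows, compares the
#' empirical percentile of the data with the model's smoothed centile at the
#' bin's mean GA.
#'
#' @param table IDP data.frame with `ga_weeks`.
#' @param idp IDP column name.
#' @param model a fitted [fp_growth_model()].
#' @param centiles centiles to compare, in percent.
#' @param min_n minimum rows per week bin; sparser bins are reported missing.
#' @return data.frame with ga_week, centile_p, empirical_value,
#'   smoothed_value, difference, and the difference in GA-specific SD units.
#' @export
empirical_vs_smoothed <- function(table, idp, model, centiles = c(3, 50, 97),
                                  min_n = 30) {
  bin <- floor(table$ga_weeks)
  weeks <- sort(unique(bin))
  rows <- list()
  for (wk in weeks) {
    sel <- bin == wk
    n <- sum(sel)
    ga0 <- mean(table$ga_weeks[sel])
    for (p in centiles) {
      emp <- if (n >= min_n) unname(quantile(table[[idp]][sel], p / 100))
        else NA_real_
      smo <- predict_centile(model, ga0, p / 100)
      rows[[length(rows) + 1]] <- data.frame(
        ga_week = wk, centile_p = p, n = n,
        empirical_value = emp, smoothed_value = smo,
        difference = emp - smo,
        difference_sd = (emp - smo) / predict_sd(model, ga0))
    }
  }
  do.call(rbind, rows)
}
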