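ssd_windows <- function() {
  # 18+0 to 20+6, 21+0 to 23+6, 24+0 to 26+6 (upper bounds exclusive at +7d)
  list("18+0-20+6" = c(18, 21), "21+0-23+6" = c(21, 24), "24+0-26+6" = c(24, 27))
}

#' Standardised site differences
#'
#' Gestational-age adjustment via z-scores from the pooled growth standard;
#' within each of the three 3-week windows, a site's SSD is the mean z-score
#' of its scans minus the window's pooled mean z-score, i.e. the site's
#' deviation from the pooled mean in pooled-SD units.
#'
#' @param table IDP data.frame with `site` and `ga_weeks` columns.
#' @param idp IDP column name.
#' @param model pooled [fp_growth_model()] for the IDP.
#' @return an `ssd_report` data.frame with site, idp, window, n_site, ssd
#'   (sites absent from a window are reported with `ssd = NA`).
#' @export
compute_ssd <- function(table, idp, model) {
  abort_if(length(unique(table$site)) < 2, "need at least 2 sites")
  z <- zscore(model, table$ga_weeks, table[[idp]])
  wins <- ssd_windows()
  out <- list()
  for (wn in names(wins)) {
    w <- wins[[wn]]
    inw <- table$ga_weeks >= w[1] & table$ga_weeks < w[2]
    pooled_mean <- if (any(inw)) mean(z[inw]) else NA_real_
    for (s in sort(unique(table$site))) {
      sel <- inw & table$site == s
      out[[length(out) + 1]] <- data.frame(
        site = s, idp = idp, window = wn, n_site = sum(sel),
        ssd = if (any(sel)) mean(z[sel]) - pooled_mean else NA_real_)
    }
  }
  rep <- do.call(rbind, out)
  class(rep) <- c("ssd_report", "data.frame")
  rep
}

#' Summarise an SSD report against the poolability bound
#'
#' Counts the site-by-window entries whose |SSD| lies within `bound` pooled
#' SD units (the prespecified adequacy interval is +/- 0.5).
#'
#' @param report an `ssd_report` (possibly row-bound over several IDPs).
#' @param bound adequacy bound in pooled-SD units.
#' @return list with `n_within`, `n_total` and `fraction_within` (NaN for an
#'   empty report).
#' @export
flag_ssd <- function(report, bound = 0.5) {
  vals <- report$ssd[!is.na(report$ssd)]
  list(n_within = sum(abs(vals) <= bound), n_total = length(vals),
       fraction_within = if (length(vals) > 0)
         sum(abs(vals) <= bound) / length(vals) else NaN)
}

#' Between-site variance components
#'
#' Random-intercept model for one IDP with sex and gestational-age terms as
#' fixed effects (GA enters with the same fractional-polynomial powers as the
#' pooled mean model) and study site as a random effect, fitted by restricted
#' maximum likelihood.  Reports the percentage of total variance attributable
#' to between-site differences.
#'
#' @param table IDP data.frame with `site`, `sex`, `ga_weeks`.
#' @param idp IDP column name.
#' @param powers GA fixed-effect powers; by default those selected by a
#'   pooled fractional-polynomial fit of the IDP.
#' @return list with `site_variance_fraction` (percent), `site_variance`,
#'   `residual_variance`, `total_variance` and the fitted `model`.
#' @export
variance_components <- function(table, idp, powers = NULL) {
  abort_if(length(unique(table$site)) < 3, "need at least 3 sites")
  tab <- table[complete.cases(table[, c("site", "sex", "ga_weeks", idp)]), ]
  n_per_site <- table(tab$site)
  abort_if(any(n_per_site < 10), "need at least 10 scans per site")
  if (is.null(powers))
    powers <- fit_fp_mean(tab$ga_weeks, tab[[idp]])$powers
  X <- fp_design(tab$ga_weeks, powers)
  # unit-scaled GA terms: fixed-effect scaling leaves the variance
  # components unchanged but keeps the optimizer well-conditioned
  dat <- data.frame(y = tab[[idp]], sex = factor(tab$sex),
                    ga1 = drop(scale(X[, 1])), ga2 = drop(scale(X[, 2])),
                    site = factor(tab$site))
  fit <- lme4::lmer(y ~ sex + ga1 + ga2 + (1 | site), data = dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_site <- vc$vcov[vc$grp == "site"]
  v_res <- vc$vcov[vc$grp == "Residual"]
  list(site_variance_fraction = 100 * v_site / (v_site + v_res),
       site_variance = v_site, residual_variance = v_res,
       total_variance = v_site + v_res, model = fit)
}

#' Leave-one-site-out centile sensitivity
#'
#' Refits the growth standard excluding each site in turn and reports, per
#' site, the maximum absolute shift of the 3rd, 50th and 97th centiles over
#' the GA domain, in pooled-SD units.
#'
#' @param table IDP data.frame with `site` and `ga_weeks`.
#' @param idp IDP column name.
#' @param centiles centiles (percent) to monitor.
#' @param ga_step evaluation grid step in weeks.
#' @return data.frame with site, centile_p and max_abs_shift_sd.
#' @export
leave_one_site_out <- function(table, idp, centiles = c(3, 50, 97),
                               ga_step = 0.25) {
  sites <- sort(unique(table$site))
  if (length(sites) < 3)
    warning("fewer than 3 sites: leave-one-out pools very little data")
  pooled <- fit_growth_model(table$ga_weeks, table[[idp]])
  grid <- seq(pooled$ga_domain[1], pooled$ga_domain[2], by = ga_step)
  sd_grid <- predict_sd(pooled, grid)
  out <- list()
  for (s in sites) {
    sub <- table[table$site != s, ]
    m <- fit_growth_model(sub$ga_weeks, sub[[idp]])
    for (p in centiles) {
      shift <- (predict_centile(m, grid, p / 100) -
                  predict_centile(pooled, grid, p / 100)) / sd_grid
      out[[length(out) + 1]] <- data.frame(
        site = s, centile_p = p, max_abs_shift_sd = max(abs(shift)),
        mean_shift_sd = mean(shift))
    }
  }
  do.call(rbind, out)
}
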