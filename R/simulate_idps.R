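#' Names of the 28 image-derived phenotypes
#'
#' Eleven structure volumes, cortical plate surface area, Sylvian fissure
#' depth, five lobe volumes, five lobe depths and five lobe thicknesses.
#'
#' @return character vector of length 28.
#' @export
idp_names <- function() {
  c("TBV", "CoPV", "WMV", "DGMV", "CBV", "ThV", "LVV", "ChPV", "FHV", "BSV",
    "CSPV", "CoPSA", "SFD",
    "FLV", "TLV", "PLV", "OLV", "ILV",
    "FLD", "TLD", "PLD", "OLD", "ILD",
    "FLT", "TLT", "PLT", "OLT", "ILT")
}

#' Default per-IDP scale fractions for the table simulator
#'
#' Each simulated IDP follows the reference TBV growth pattern scaled by a
#' constant fraction (a statistical emulation, not anatomy): the generator's
#' purpose is to give every downstream statistic a known mean/SD/confound
#' structure.
#'
#' @return named numeric vector over [idp_names()].
#' @export
default_fraction_curves <- function() {
  c(TBV = 1, CoPV = 0.10, WMV = 0.25, DGMV = 0.020, CBV = 0.012,
    ThV = 0.005, LVV = 0.004, ChPV = 0.003, FHV = 0.002, BSV = 0.008,
    CSPV = 0.0015, CoPSA = 0.9, SFD = 0.010,
    FLV = 0.030, TLV = 0.020, PLV = 0.022, OLV = 0.015, ILV = 0.008,
    FLD = 0.012, TLD = 0.011, PLD = 0.012, OLD = 0.010, ILD = 0.013,
    FLT = 0.0020, TLT = 0.0021, PLT = 0.0019, OLT = 0.0020, ILT = 0.0022)
}

#' Configuration for the IDP table simulator
#'
#' @param n_fetuses number of fetuses.
#' @param mean_model growth model for the TBV mean/SD pattern
#'   (default [tbv_reference_model()]).
#' @param fraction_curves named per-IDP scale fractions
#'   (default [default_fraction_curves()]).
#' @param site_proportions named site sampling fractions.
#' @param confound_effects list with `site` (named per-site offsets in
#'   GA-specific SD units), `sex` (offset added for males) and `hemisphere`
#'   (offset added for right-hemisphere scans).
#' @param noise "ga_varying" draws Gaussian noise with the model's
#'   exponentiated log-SD curve; "constant" uses the SD at the domain
#'   midpoint (a pure random-intercept structure); "none" is deterministic.
#' @param visit_gas optional list of fixed visit gestational ages per fetus;
#'   when NULL the protocol schedule (first visit U\[14,18\], +5 +/- 1 weeks)
#'   is used and only in-window visits are kept.
#' @param ga_range gestational-age window in weeks.
#' @param p_male,p_right sampling probabilities for sex and visible
#'   hemisphere (rightward head position is the more common presentation).
#' @param seed integer seed.
#' @return a `sim_table_config` list.
#' @export
sim_table_config <- function(n_fetuses,
                             mean_model = tbv_reference_model(),
                             fraction_curves = default_fraction_curves(),
                             site_proportions = default_site_proportions(),
                             confound_effects = list(site = NULL, sex = 0,
                                                     hemisphere = 0),
                             noise = c("ga_varying", "constant", "none"),
                             visit_gas = NULL,
                             ga_range = c(18, 27),
                             p_male = 0.5, p_right = 0.6,
                             seed = 1L) {
  noise <- match.arg(noise)
  abort_if(!all(idp_names() %in% names(fraction_curves)),
           "fraction_curves must cover all 28 IDPs")
  if (is.null(confound_effects$site))
    confound_effects$site <- stats::setNames(rep(0, length(site_proportions)),
                                             names(site_proportions))
  abort_if(!all(is.finite(unlist(confound_effects))),
           "confound offsets must be finite")
  abort_if(any(predict_sd(mean_model, seq(ga_range[1], ga_range[2],
                                          length.out = 11)) <= 0),
           "noise SD must be positive on the GA domain")
  if (!is.null(visit_gas)) {
    gas <- unlist(visit_gas)
    abort_if(any(gas < mean_model$ga_domain[1] | gas > mean_model$ga_domain[2]),
             "visit gestational ages outside the growth-model domain")
  }
  structure(list(n_fetuses = as.integer(n_fetuses), mean_model = mean_model,
                 fraction_curves = fraction_curves,
                 site_proportions = site_proportions,
                 confound_effects = confound_effects, noise = noise,
                 visit_gas = visit_gas, ga_range = ga_range,
                 p_male = p_male, p_right = p_right, seed = as.integer(seed)),
            class = "sim_table_config")
}

#' Simulate an IDP table with known structure
#'
#' One row per scan.  Each IDP value is
#' `f * (mean(GA) + (site + sex + hemisphere offsets) * SD(GA) + e * SD(GA))`
#' with `f` the IDP's scale fraction and `e` standard Gaussian noise (the SD
#' is GA-varying, constant, or zero per the configuration), so GA-adjusted
#' site means, variance fractions and growth-curve coefficients are known by
#' construction.  Deterministic given the seed.
#'
#' @param cfg a [sim_table_config()].
#' @return a data.frame with metadata columns (fetus_id, site, sex, ga_weeks,
#'   hemisphere) and the 28 IDP columns.
#' @export
simulate_idp_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_table_config"))
  set.seed(cfg$seed)
  n <- cfg$n_fetuses
  sites <- sample(names(cfg$site_proportions), n, replace = TRUE,
                  prob = cfg$site_proportions)
  sexes <- ifelse(runif(n) < cfg$p_male, "male", "female")
  if (is.null(cfg$visit_gas)) {
    schedules <- protocol_schedule(n)
    schedules <- lapply(schedules, function(g)
      g[g >= cfg$ga_range[1] & g <= cfg$ga_range[2]])
  } else {
    schedules <- rep_len(cfg$visit_gas, n)
  }
  n_visits <- lengths(schedules)
  rows <- data.frame(
    fetus_id = rep(sprintf("F%05d", seq_len(n)), n_visits),
    site = rep(sites, n_visits),
    sex = rep(sexes, n_visits),
    ga_weeks = unlist(schedules),
    stringsAsFactors = FALSE)
  rows$hemisphere <- ifelse(runif(nrow(rows)) < cfg$p_right, "right", "left")

  mu <- predict_mean(cfg$mean_model, rows$ga_weeks)
  sd_ga <- switch(cfg$noise,
                  ga_varying = predict_sd(cfg$mean_model, rows$ga_weeks),
                  constant = rep(predict_sd(cfg$mean_model,
                                            mean(cfg$ga_range)), nrow(rows)),
                  none = rep(predict_sd(cfg$mean_model,
                                        mean(cfg$ga_range)), nrow(rows)))
  offset <- cfg$confound_effects$site[rows$site] +
    cfg$confound_effects$sex * (rows$sex == "male") +
    cfg$confound_effects$hemisphere * (rows$hemisphere == "right")
  for (idp in idp_names()) {
    f <- cfg$fraction_curves[[idp]]
    eps <- if (cfg$noise == "none") 0 else rnorm(nrow(rows))
    rows[[idp]] <- f * (mu + (offset + eps) * sd_ga)
  }
  rows
}
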