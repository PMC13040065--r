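#' Fractional-polynomial growth model objects
#'
#' A normative growth standard for one IDP: a degree-2 fractional-polynomial
#' mean curve over gestational age (GA, weeks) plus a log-linear SD curve
#' (the SD equation is on the log scale and must be exponentiated).
#'
#' @param powers numeric length-2, the ordered FP power pair (0 means log GA;
#'   a repeated power p uses GA^p and GA^p * log GA).
#' @param mean_coeffs numeric length-3: intercept and the two FP coefficients.
#' @param sd_coeffs numeric length-2: intercept and slope of log SD vs GA.
#' @param ga_domain numeric length-2 GA domain in weeks; no extrapolation is
#'   allowed outside it.
#' @param n_fitted number of observations the model was fitted on.
#' @return an object of class `fp_growth_model`.
#' @export
fp_growth_model <- function(powers, mean_coeffs, sd_coeffs,
                            ga_domain = c(18, 27), n_fitted = NA_integer_) {
  abort_if(length(powers) != 2 || length(mean_coeffs) != 3 ||
             length(sd_coeffs) != 2, "malformed growth model components")
  m <- structure(
    list(powers = as.numeric(powers),
         mean_coeffs = as.numeric(mean_coeffs),
         sd_coeffs = as.numeric(sd_coeffs),
         ga_domain = as.numeric(ga_domain),
         n_fitted = n_fitted),
    class = "fp_growth_model")
  abort_if(any(!is.finite(predict_mean(m, seq(ga_domain[1], ga_domain[2],
                                              length.out = 21)))),
           "mean curve not finite on the GA domain")
  m
}

#' @export
print.fp_growth_model <- function(x, ...) {
  cat("Fractional-polynomial growth model\n")
  cat(sprintf("  powers: (%g, %g)\n", x$powers[1], x$powers[2]))
  term <- function(p) if (p == 0) "log(GA)" else sprintf("GA^%g", p)
  t2 <- if (x$powers[1] == x$powers[2])
    paste0(term(x$powers[2]), "*log(GA)") else term(x$powers[2])
  cat(sprintf("  mean:   %.6f + %.6f*%s + %.6f*%s\n",
              x$mean_coeffs[1], x$mean_coeffs[2], term(x$powers[1]),
              x$mean_coeffs[3], t2))
  cat(sprintf("  log SD: %.6f + %.6f*GA (exponentiate for SD)\n",
              x$sd_coeffs[1], x$sd_coeffs[2]))
  cat(sprintf("  GA domain: [%g, %g] weeks, n = %s\n",
              x$ga_domain[1], x$ga_domain[2], x$n_fitted))
  invisible(x)
}

# one fractional-polynomial basis term; power 0 is log(ga)
fp_term <- function(ga, p) if (p == 0) log(ga) else ga^p

# design matrix (without intercept) for an FP power pair
fp_design <- function(ga, powers) {
  x1 <- fp_term(ga, powers[1])
  x2 <- if (powers[1] == powers[2]) x1 * log(ga) else fp_term(ga, powers[2])
  cbind(x1, x2)
}

check_domain <- function(model, ga) {
  abort_if(any(ga < model$ga_domain[1] - 1e-9 | ga > model$ga_domain[2] + 1e-9),
           sprintf("gestational age outside the model domain [%g, %g]",
                   model$ga_domain[1], model$ga_domain[2]))
}

#' Evaluate the mean and SD curves of a growth model
#'
#' @param model an [fp_growth_model()].
#' @param ga gestational ages in weeks, within the model domain.
#' @return `predict_mean` the mean curve; `predict_sd` the (exponentiated) SD.
#' @export
predict_mean <- function(model, ga) {
  X <- fp_design(ga, model$powers)
  drop(model$mean_coeffs[1] + X %*% model$mean_coeffs[2:3])
}

#' @rdname predict_mean
#' @export
predict_sd <- function(model, ga) {
  exp(model$sd_coeffs[1] + model$sd_coeffs[2] * ga)
}

#' Reference total-brain-volume growth standard
#'
#' The published TBV growth equation used as the anchor of the synthetic-data
#' module: mean(GA) = 1.954510 + 0.018205 GA^3 - 0.178633 GA^2 (cm^3) and
#' log SD(GA) = -0.702623 + 0.150265 GA, over 18-27 weeks.
#'
#' @return an [fp_growth_model()] for TBV (units cm^3).
#' @export
tbv_reference_model <- function() {
  fp_growth_model(powers = c(2, 3),
                  mean_coeffs = c(1.954510, -0.178633, 0.018205),
                  sd_coeffs = c(-0.702623, 0.150265),
                  ga_domain = c(18, 27), n_fitted = 4196L)
}

#' Serialise growth models as JSON
#'
#' @param model an [fp_growth_model()].
#' @param path file path.
#' @return `read_growth_model` returns the model; `write_growth_model` the
#'   path, invisibly.
#' @export
write_growth_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_growth_model
#' @export
read_growth_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fp_growth_model(x$powers, x$mean_coeffs, x$sd_coeffs, x$ga_domain,
                  if (is.null(x$n_fitted)) NA_integer_ else x$n_fitted)
}
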