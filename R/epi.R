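#' Population attributable fraction
#'
#' Share of deaths attributable to an exposure with prevalence \code{p} and
#' relative risk \code{RR}: \eqn{p(RR-1) / (1 + p(RR-1))}. Used as the
#' affected fraction for interventions whose benefit is confined to stillbirths
#' caused by a measurable risk factor (untreated syphilis, diabetes, severe
#' hypertensive disorders, placental malaria, prolonged pregnancy).
#'
#' A protective exposure (\code{RR < 1}) would give a negative attributable
#' fraction; since an affected fraction is a proportion of deaths, the result
#' is clamped at 0.
#'
#' @param prevalence Exposure prevalence, fraction in \code{[0, 1]}.
#' @param relative_risk Relative risk of stillbirth among the exposed, > 0.
#' @return Attributable fraction in \code{[0, 1)}.
#' @examples
#' paf(0.075, 1.8)   # stillbirths attributable to prolonged pregnancy
#' @export
paf <- function(prevalence, relative_risk) {
  check_fraction(prevalence, "prevalence")
  if (!is.numeric(relative_risk) || any(!is.finite(relative_risk)) ||
      any(relative_risk <= 0)) {
    stop("relative_risk must be a positive finite number", call. = FALSE)
  }
  excess <- prevalence * (relative_risk - 1)
  pmax(0, excess / (1 + excess))
}

#' Prevalence-proxy affected fraction
#'
#' When no excess-risk estimate exists for a risk factor, the stillbirth risk
#' among the exposed is assumed equal to the general population's, so the
#' affected fraction is simply the exposure prevalence (a conservative
#' understatement when the exposed are in fact at higher risk). Used for
#' balanced energy supplementation, where the poverty headcount proxies the
#' food-insecure share.
#'
#' @param prevalence Exposure prevalence, fraction in \code{[0, 1]}.
#' @return \code{prevalence}, unchanged.
#' @export
prevalence_proxy_af <- function(prevalence) {
  check_fraction(prevalence, "prevalence")
  prevalence
}

#' Affected fraction for malaria prevention
#'
#' Stillbirths attributable to falciparum malaria: the fraction of pregnant
#' women exposed to falciparum malaria is first scaled by the placental-malaria
#' rate among the exposed, and the result fed into \code{\link{paf}} with the
#' placental-malaria odds ratio treated as a relative-risk approximation
#' (stillbirth is rare enough for the two to be interchangeable).
#'
#' The default placental rate 0.278 is the primigravida figure; rates of 0.208
#' (second pregnancies) and 0.156 (higher-order) may be substituted, so the
#' default can overestimate the attributable fraction.
#'
#' @param exposure_fraction Fraction of pregnant women exposed to falciparum
#'   malaria.
#' @param placental_rate Placental-malaria rate among the exposed.
#' @param odds_ratio Odds ratio of stillbirth with placental malaria.
#' @return Attributable fraction in \code{[0, 1)}.
#' @export
malaria_af <- function(exposure_fraction, placental_rate = 0.278,
                       odds_ratio = 2.19) {
  check_fraction(exposure_fraction, "exposure_fraction")
  check_fraction(placental_rate, "placental_rate")
  paf(exposure_fraction * placental_rate, odds_ratio)
}

#' Resolve the affected fraction for an intervention in a country
#'
#' Dispatches an \code{\link{af_spec}} against a \code{\link{country_profile}}:
#' \code{ALL} gives 1, \code{PREVALENCE_PROXY} returns the named prevalence,
#' \code{PAF} and \code{MALARIA_COMPOSITE} compute attributable fractions from
#' the named prevalence and the spec's relative risk.
#'
#' @param spec An \code{\link{af_spec}}.
#' @param profile A \code{\link{country_profile}} supplying the prevalence the
#'   spec names.
#' @param timing \code{"antepartum"} or \code{"intrapartum"}.
#' @return A list of class \code{"affected_fraction"} with fields
#'   \code{value}, \code{timing}, \code{rule_used}.
#' @export
resolve_affected_fraction <- function(spec, profile,
                                      timing = c("antepartum", "intrapartum")) {
  timing <- match.arg(timing)
  get_prev <- function() {
    key <- spec$prevalence_key
    p <- profile$prevalences[[key]]
    if (is.null(p)) {
      stop(sprintf("profile is missing prevalence field '%s' required by rule %s",
                   key, spec$rule), call. = FALSE)
    }
    p
  }
  value <- switch(spec$rule,
    ALL = 1.0,
    PREVALENCE_PROXY = prevalence_proxy_af(get_prev()),
    PAF = paf(get_prev(), spec$relative_risk),
    MALARIA_COMPOSITE = malaria_af(
      get_prev(),
      placental_rate = spec$extra$placental_rate %||% 0.278,
      odds_ratio = spec$relative_risk
    ),
    stop(sprintf("unknown affected-fraction rule '%s'", spec$rule), call. = FALSE)
  )
  structure(list(value = value, timing = timing, rule_used = spec$rule),
            class = "affected_fraction")
}

check_fraction <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must be a fraction in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
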