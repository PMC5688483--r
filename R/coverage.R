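#' Childbirth delivery mix
#'
#' Partition of all births across the four mutually exclusive childbirth-care
#' categories: home delivery without a skilled attendant, skilled attendance
#' outside BEmOC/CEmOC facilities, BEmOC facility delivery, and CEmOC facility
#' delivery. Shares must sum to 1.
#'
#' @param home_no_sba,sba_outside,bemoc,cemoc Fractions of all births.
#' @return A list of class \code{"childbirth_mix"}.
#' @export
childbirth_mix <- function(home_no_sba, sba_outside, bemoc, cemoc) {
  mix <- list(home_no_sba = home_no_sba, sba_outside = sba_outside,
              bemoc = bemoc, cemoc = cemoc)
  for (nm in names(mix)) check_fraction(mix[[nm]], nm)
  total <- sum(unlist(mix))
  if (abs(total - 1) > 1e-9) {
    stop(sprintf("childbirth mix must sum to 1 (got %.12f)", total),
         call. = FALSE)
  }
  structure(mix, class = "childbirth_mix")
}

#' @export
print.childbirth_mix <- function(x, ...) {
  cat("<childbirth_mix>",
      sprintf("%s=%.3f", names(x), unlist(x)), "\n")
  invisible(x)
}

#' Syphilis detection-and-treatment coverage proxy from ANC4+
#'
#' No country-level coverage data exist for syphilis screening in pregnancy;
#' coverage is assumed to be a step-dependent share of women attending four or
#' more antenatal visits: 20% of ANC4+ where ANC4+ is below 40%, 50% up to
#' 75%, 70% up to 95%, and 100% above 95%. Boundaries are assigned to the
#' upper tier.
#'
#' @param anc4 ANC4+ coverage, fraction in \code{[0, 1]}.
#' @return Estimated syphilis detection-and-treatment coverage.
#' @export
syphilis_coverage_from_anc4 <- function(anc4) {
  check_fraction(anc4, "anc4")
  share <- ifelse(anc4 < 0.40, 0.20,
           ifelse(anc4 < 0.75, 0.50,
           ifelse(anc4 <= 0.95, 0.70, 1.00)))
  share * anc4
}

#' ANC4-share coverage proxy for conditions managed in antenatal care
#'
#' Diabetes screening and hypertensive-disorder management are assumed to reach
#' only a small minority (5% by default) of women attending four or more
#' antenatal visits.
#'
#' @param anc4 ANC4+ coverage, fraction in \code{[0, 1]}.
#' @param share Share of ANC4+ attendees receiving the intervention.
#' @return Estimated coverage.
#' @export
anc_condition_coverage <- function(anc4, share = 0.05) {
  check_fraction(anc4, "anc4")
  check_fraction(share, "share")
  share * anc4
}

# BEmOC/CEmOC shares of facility deliveries by facility-delivery tier.
# Boundaries 0.30, 0.50, 0.95 go to the upper tier.
facility_tier_shares <- function(facility_rate) {
  if (facility_rate < 0.30) c(bemoc = 0.00, cemoc = 0.10)
  else if (facility_rate < 0.50) c(bemoc = 0.30, cemoc = 0.20)
  else if (facility_rate < 0.95) c(bemoc = 0.15, cemoc = 0.60)
  else c(bemoc = 0.00, cemoc = 1.00)
}

#' Childbirth mix from facility-delivery and skilled-attendance rates
#'
#' Emergency obstetric care coverage is not directly surveyed; the BEmOC and
#' CEmOC shares are assumed to be tier-dependent proportions of facility
#' deliveries (0%/10% below 30% facility delivery, 30%/20% up to 50%, 15%/60%
#' up to 95%, 0%/100% above). Skilled attendance outside those facilities
#' absorbs the remaining skilled births, and home delivery without a skilled
#' attendant the rest, so the four categories sum to 1. Facility births not
#' assigned to BEmOC/CEmOC are counted with skilled attendance outside
#' BEmOC/CEmOC facilities so that masses balance.
#'
#' @param facility_rate Fraction of births delivered in a facility.
#' @param sba_rate Fraction of births with a skilled attendant
#'   (\code{>= facility_rate}).
#' @return A \code{\link{childbirth_mix}}.
#' @export
childbirth_mix_from_facility <- function(facility_rate, sba_rate) {
  check_fraction(facility_rate, "facility_rate")
  check_fraction(sba_rate, "sba_rate")
  if (facility_rate > sba_rate + 1e-12) {
    stop("facility_rate cannot exceed sba_rate", call. = FALSE)
  }
  shares <- facility_tier_shares(facility_rate)
  bemoc <- shares[["bemoc"]] * facility_rate
  cemoc <- shares[["cemoc"]] * facility_rate
  sba_outside <- sba_rate - (bemoc + cemoc)
  home <- 1 - sba_rate
  v <- pmax(0, c(home, sba_outside, bemoc, cemoc))
  v <- v / sum(v)
  childbirth_mix(home_no_sba = v[1], sba_outside = v[2],
                 bemoc = v[3], cemoc = v[4])
}

#' Coverage cap for induction of labour
#'
#' Safe induction for prolonged pregnancy requires accurate dating and access
#' to emergency caesarean section, so coverage is capped at the share of births
#' occurring in CEmOC-level facilities.
#'
#' @param requested Requested induction coverage.
#' @param cemoc CEmOC delivery share of all births.
#' @return \code{min(requested, cemoc)}.
#' @export
induction_coverage_cap <- function(requested, cemoc) {
  check_fraction(requested, "requested")
  check_fraction(cemoc, "cemoc")
  pmin(requested, cemoc)
}
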