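# Independent brute-force oracle: measure the attributable fraction of deaths
# on a simulated cohort (exposure ~ Bernoulli(p); baseline death risk r,
# exposed risk r*RR). Returns the measured AF and a delta-method Monte-Carlo
# standard error. Deliberately does not use any package simulation code.
brute_force_af <- function(p, rr, n = 1e6, baseline_risk = 0.02, seed = 1) {
  set.seed(seed)
  exposed <- stats::runif(n) < p
  risk <- baseline_risk * ifelse(exposed, rr, 1)
  death <- stats::runif(n) < pmin(1, risk)
  de <- sum(death & exposed)
  du <- sum(death & !exposed)
  ne <- sum(exposed)
  total <- de + du
  af_hat <- (de - ne * baseline_risk) / total
  # delta method on (de, du), conditioning on the exposure draws
  var_de <- ne * baseline_risk * rr * (1 - baseline_risk * rr)
  var_du <- (n - ne) * baseline_risk * (1 - baseline_risk)
  d_de <- (du + ne * baseline_risk) / total^2
  d_du <- -(de - ne * baseline_risk) / total^2
  se <- sqrt(d_de^2 * var_de + d_du^2 * var_du)
  list(af = af_hat, se = se, deaths = total)
}

# A profile crafted so the antepartum compartment holds exactly `attributable`
# stillbirths attributable to untreated syphilis, with every other risk factor
# and baseline coverage switched off.
syphilis_example_profile <- function(attributable = 1000) {
  af <- paf(0.05, 10.89)
  env_ap <- attributable / af
  country_profile(
    births_per_year = 1e6,
    stillbirths = env_ap / 0.6,
    prop_intrapartum = 0.4,
    prevalences = list(untreated_syphilis = 0.05, diabetes = 0, severe_hdp = 0,
                       malaria_exposure = 0, poverty = 0,
                       prolonged_pregnancy = 0),
    baseline_indicators = list(anc4 = 0, sba = 0, facility_delivery = 0,
                               iptp_or_itn = 0)
  )
}

random_valid_profile <- function() {
  sba <- runif(1)
  country_profile(
    births_per_year = round(runif(1, 1e4, 1e6)),
    sbr = runif(1, 1, 40),
    prop_intrapartum = runif(1),
    prevalences = list(untreated_syphilis = runif(1, 0, 0.1),
                       diabetes = runif(1, 0, 0.15),
                       severe_hdp = runif(1, 0, 0.1),
                       malaria_exposure = runif(1),
                       poverty = runif(1)),
    baseline_indicators = list(anc4 = runif(1), sba = sba,
                               facility_delivery = runif(1) * sba,
                               iptp_or_itn = runif(1))
  )
}
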