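# Run code under a private RNG stream, leaving global RNG state untouched.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Microsimulation configuration
#'
#' Inputs for one simulated pregnancy cohort: cohort size, seed, per-pregnancy
#' baseline stillbirth risks by timing (the risk of an unexposed pregnancy
#' delivered at home without a skilled attendant), a country profile supplying
#' the risk-factor prevalences, intervention coverage, and the childbirth
#' delivery mix.
#'
#' @param n Cohort size (>= 1).
#' @param seed RNG seed; the whole cohort is determined by it.
#' @param baseline_risk_ap,baseline_risk_ip Baseline antepartum / intrapartum
#'   stillbirth probabilities in \code{[0, 1]}.
#' @param profile A \code{\link{country_profile}} (prevalences are used).
#' @param coverage Named list: intervention id -> coverage fraction
#'   (missing ids default to 0).
#' @param mix \code{\link{childbirth_mix}} of delivery categories (default:
#'   all home without a skilled attendant).
#' @param registry Intervention registry.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n, seed, baseline_risk_ap, baseline_risk_ip,
                       profile, coverage = list(),
                       mix = childbirth_mix(1, 0, 0, 0),
                       registry = load_default_interventions()) {
  stopifnot(is.numeric(n), n >= 1)
  check_fraction(baseline_risk_ap, "baseline_risk_ap")
  check_fraction(baseline_risk_ip, "baseline_risk_ip")
  stopifnot(inherits(profile, "country_profile"), inherits(mix, "childbirth_mix"))
  for (nm in names(coverage)) check_fraction(coverage[[nm]], nm)
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         baseline_risk_ap = baseline_risk_ap,
         baseline_risk_ip = baseline_risk_ip,
         profile = profile, coverage = coverage, mix = mix,
         registry = registry),
    class = "sim_config"
  )
}

#' Simulate an individual-level pregnancy cohort
#'
#' Monte-Carlo oracle for the deterministic arithmetic. Each pregnancy draws
#' its risk-factor exposures as independent Bernoulli variables at the profile
#' prevalences, its intervention receipt as independent Bernoulli variables at
#' the configured coverages, and a delivery category from the childbirth mix.
#' Exposures with a known excess risk multiply the baseline stillbirth risk by
#' the relative risk; a received intervention removes a fraction
#' (effectiveness) of that \emph{excess} risk. Interventions whose affected
#' fraction is everyone (or a prevalence proxy with no excess risk) instead
#' scale the whole risk of affected pregnancies by one minus effectiveness.
#' Delivery categories scale the intrapartum risk by one minus the category
#' effectiveness relative to home birth. Risks multiply on the probability
#' scale and are clamped at 1. Outcomes are drawn sequentially: antepartum
#' stillbirth first, intrapartum stillbirth among survivors of labour onset,
#' livebirth otherwise.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{counts} (named: livebirth, antepartum_sb,
#'   intrapartum_sb), \code{strata} (data.frame of outcome counts by
#'   risk-factor exposure stratum), \code{n} and \code{seed}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  prev <- config$profile$prevalences
  eff_cb <- childbirth_effects(config$registry)

  with_seed(config$seed, {
    mult_ap <- rep(1, n)
    mult_ip <- rep(1, n)
    exposures <- list()

    for (spec in config$registry) {
      if (spec$status != "current" || spec$coverage_rule == "CHILDBIRTH_MIX") next
      cov <- config$coverage[[spec$id]] %||% 0
      received <- stats::runif(n) < cov
      af <- spec$af
      rr <- af$relative_risk
      exposed <- switch(af$rule,
        ALL = rep(TRUE, n),
        PREVALENCE_PROXY = stats::runif(n) < prev[[af$prevalence_key]],
        PAF = stats::runif(n) < prev[[af$prevalence_key]],
        MALARIA_COMPOSITE = (stats::runif(n) < prev[[af$prevalence_key]]) &
          (stats::runif(n) < (af$extra$placental_rate %||% 0.278))
      )
      if (af$rule %in% c("PAF", "MALARIA_COMPOSITE")) {
        exposures[[af$prevalence_key]] <- exposed
      }
      for (timing in c("ap", "ip")) {
        eff <- spec[[if (timing == "ap") "antepartum_effect" else
                     "intrapartum_effect"]]
        if (is.null(eff)) next
        m <- if (af$rule %in% c("PAF", "MALARIA_COMPOSITE")) {
          # exposed risk r*(1 + (RR-1)*(1-e)) if treated, r*RR otherwise
          1 + (rr - 1) * (1 - eff$point * received) * exposed
        } else {
          1 - eff$point * received * exposed
        }
        if (timing == "ap") mult_ap <- mult_ap * m else mult_ip <- mult_ip * m
      }
    }

    # delivery category from the childbirth mix; intrapartum risk scaled by
    # one minus the category effectiveness
    cuts <- cumsum(unlist(config$mix)[names(eff_cb)])
    category <- names(eff_cb)[findInterval(stats::runif(n), c(0, cuts),
                                           rightmost.closed = TRUE)]
    mult_ip <- mult_ip * (1 - eff_cb[category])

    p_ap <- pmin(1, config$baseline_risk_ap * mult_ap)
    p_ip <- pmin(1, config$baseline_risk_ip * mult_ip)
    ap_sb <- stats::runif(n) < p_ap
    ip_sb <- !ap_sb & (stats::runif(n) < p_ip)

    strata <- do.call(rbind, lapply(names(exposures), function(id) {
      e <- exposures[[id]]
      data.frame(
        factor = id,
        exposed = c(TRUE, FALSE),
        n = c(sum(e), sum(!e)),
        antepartum_sb = c(sum(ap_sb & e), sum(ap_sb & !e)),
        intrapartum_sb = c(sum(ip_sb & e), sum(ip_sb & !e))
      )
    }))

    list(
      counts = c(livebirth = sum(!ap_sb & !ip_sb),
                 antepartum_sb = sum(ap_sb),
                 intrapartum_sb = sum(ip_sb)),
      strata = strata, n = n, seed = config$seed
    )
  })
}

#' Generate a synthetic country profile
#'
#' Emits a fully populated, valid \code{\link{country_profile}} with
#' archetype-plausible parameter ranges, deterministically per seed. The
#' archetypes sketch the global spread of stillbirth settings: high-burden
#' (SBR 20-35, low ANC4/skilled attendance, endemic malaria, widespread
#' poverty), transition (SBR 12-20, intermediate coverage), and low-burden
#' (SBR 3-10, near-universal facility delivery, no malaria). Profiles are
#' synthetic fixtures, not estimates for any real country.
#'
#' @param seed RNG seed.
#' @param archetype One of \code{"high-burden"}, \code{"transition"},
#'   \code{"low-burden"}.
#' @return A \code{\link{country_profile}}.
#' @export
generate_profile_fixture <- function(seed,
                                     archetype = c("high-burden", "transition",
                                                   "low-burden")) {
  archetype <- match.arg(archetype)
  r <- switch(archetype,
    "high-burden" = list(
      sbr = c(20, 35), prop_ip = c(0.30, 0.50), anc4 = c(0.30, 0.60),
      sba = c(0.30, 0.60), fac_of_sba = c(0.50, 0.90), iptp = c(0.10, 0.50),
      syphilis = c(0.010, 0.050), diabetes = c(0.020, 0.080),
      hdp = c(0.010, 0.050), malaria = c(0.20, 0.60), poverty = c(0.30, 0.70),
      births = c(2e5, 2e6)
    ),
    "transition" = list(
      sbr = c(12, 20), prop_ip = c(0.15, 0.35), anc4 = c(0.50, 0.80),
      sba = c(0.55, 0.90), fac_of_sba = c(0.60, 0.95), iptp = c(0.00, 0.30),
      syphilis = c(0.005, 0.020), diabetes = c(0.030, 0.100),
      hdp = c(0.010, 0.040), malaria = c(0.00, 0.20), poverty = c(0.05, 0.30),
      births = c(1e5, 1e6)
    ),
    "low-burden" = list(
      sbr = c(3, 10), prop_ip = c(0.05, 0.15), anc4 = c(0.80, 0.99),
      sba = c(0.90, 1.00), fac_of_sba = c(0.85, 1.00), iptp = c(0, 0),
      syphilis = c(0.001, 0.005), diabetes = c(0.050, 0.120),
      hdp = c(0.010, 0.030), malaria = c(0, 0), poverty = c(0.00, 0.05),
      births = c(5e4, 5e5)
    )
  )
  u <- function(lim) stats::runif(1, lim[1], lim[2])
  with_seed(seed, {
    sba <- u(r$sba)
    country_profile(
      births_per_year = round(u(r$births)),
      sbr = u(r$sbr),
      prop_intrapartum = u(r$prop_ip),
      prevalences = list(
        untreated_syphilis = u(r$syphilis), diabetes = u(r$diabetes),
        severe_hdp = u(r$hdp), malaria_exposure = u(r$malaria),
        poverty = u(r$poverty)
      ),
      baseline_indicators = list(
        anc4 = u(r$anc4), sba = sba,
        facility_delivery = sba * u(r$fac_of_sba), iptp_or_itn = u(r$iptp)
      ),
      name = sprintf("synthetic-%s-%d", archetype, seed)
    )
  })
}

#' Compare the deterministic engine against the microsimulation
#'
#' For each intervention, scales coverage up from zero in an individual-level
#' cohort and checks that the simulated reduction in stillbirths matches the
#' deterministic prediction (effectiveness x coverage change x affected
#' fraction, applied to the simulated baseline death counts). Childbirth-care
#' categories are exercised by moving a share of births from home delivery to
#' each category in turn. Scale-ups start at zero baseline coverage with an
#' all-home delivery mix, the regime in which the linear non-renormalised
#' arithmetic is exact. The coverage cap on induction is a policy constraint
#' on scenarios, not part of the averted-deaths arithmetic, and is not applied
#' here.
#'
#' @param profile A \code{\link{country_profile}} (prevalences are used; the
#'   baseline per-pregnancy risks are derived from its stillbirth rate and
#'   timing split).
#' @param registry Intervention registry.
#' @param n Cohort size per simulation run.
#' @param seed RNG seed; each run uses an offset of it.
#' @param target_cov Coverage (or mix share) reached by each scale-up.
#' @return Data.frame with one row per intervention x timing: the target
#'   coverage, the engine-predicted and simulated averted counts, the
#'   Monte-Carlo standard error of their difference, and the z-score.
#' @export
engine_microsim_agreement <- function(profile,
                                      registry = load_default_interventions(),
                                      n = 1e6, seed = 1, target_cov = 0.8) {
  p_total <- sbr(profile$stillbirths, profile$births_per_year) / 1000
  risk_ip <- p_total * profile$prop_intrapartum
  risk_ap <- p_total - risk_ip

  base_cfg <- function(seed, coverage = list(), mix = childbirth_mix(1, 0, 0, 0)) {
    sim_config(n = n, seed = seed, baseline_risk_ap = risk_ap,
               baseline_risk_ip = risk_ip, profile = profile,
               coverage = coverage, mix = mix, registry = registry)
  }
  d0 <- simulate_cohort(base_cfg(seed))$counts

  rows <- list()
  compare <- function(id, timing, f, d0_t, d1_t) {
    engine_averted <- f * d0_t
    sim_averted <- d0_t - d1_t
    se <- sqrt((1 - f)^2 * d0_t + d1_t)
    rows[[length(rows) + 1L]] <<- data.frame(
      intervention = id, timing = timing, target_cov = target_cov,
      engine_averted = engine_averted, sim_averted = sim_averted,
      se = se, z = if (se > 0) (sim_averted - engine_averted) / se else 0
    )
  }

  k <- 0L
  for (spec in registry) {
    if (spec$status != "current" || spec$coverage_rule == "CHILDBIRTH_MIX") next
    k <- k + 1L
    cov <- stats::setNames(list(target_cov), spec$id)
    d1 <- simulate_cohort(base_cfg(seed + k, coverage = cov))$counts
    for (timing in c("antepartum", "intrapartum")) {
      eff <- spec[[paste0(timing, "_effect")]]
      if (is.null(eff)) next
      afr <- resolve_affected_fraction(af_for_timing(spec, timing), profile,
                                       timing)
      f <- averted_fraction(eff$point, 0, target_cov, afr$value)
      key <- if (timing == "antepartum") "antepartum_sb" else "intrapartum_sb"
      compare(spec$id, timing, f, d0[[key]], d1[[key]])
    }
  }
  eff_cb <- childbirth_effects(registry)
  for (cat in c("sba_outside", "bemoc", "cemoc")) {
    k <- k + 1L
    mix_vals <- list(home_no_sba = 1 - target_cov, sba_outside = 0,
                     bemoc = 0, cemoc = 0)
    mix_vals[[cat]] <- target_cov
    d1 <- simulate_cohort(base_cfg(seed + k, mix = do.call(childbirth_mix,
                                                           mix_vals)))$counts
    f <- eff_cb[[cat]] * target_cov  # AF = 1: all intrapartum stillbirths
    compare(cat, "intrapartum", f, d0[["intrapartum_sb"]],
            d1[["intrapartum_sb"]])
  }
  do.call(rbind, rows)
}

#' Oracle-agreement suite over synthetic profiles
#'
#' Runs \code{\link{engine_microsim_agreement}} over a batch of seeded
#' synthetic profiles cycling through the three archetypes and stacks the
#' results.
#'
#' @param n_profiles Number of synthetic profiles.
#' @param n Cohort size per simulation run.
#' @param seed Base RNG seed.
#' @param registry Intervention registry.
#' @return Data.frame of per-profile, per-intervention comparisons with a
#'   \code{profile} column.
#' @export
microsim_check <- function(n_profiles = 20, n = 1e6, seed = 1,
                           registry = load_default_interventions()) {
  archetypes <- c("high-burden", "transition", "low-burden")
  out <- lapply(seq_len(n_profiles), function(i) {
    prof <- generate_profile_fixture(seed + i,
                                     archetypes[(i - 1L) %% 3L + 1L])
    res <- engine_microsim_agreement(prof, registry = registry, n = n,
                                     seed = seed + 1000L * i)
    res$profile <- prof$name
    res
  })
  do.call(rbind, out)
}
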