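#' Country profile
#'
#' Demography, stillbirth envelope, timing split, risk-factor prevalences and
#' baseline coverage indicators for one country or subnational unit. The
#' stillbirth envelope (late fetal deaths at >=28 weeks or >=1000 g) may be
#' given either as a count (\code{stillbirths}) or as a rate per 1000 total
#' births (\code{sbr}); it is normalised internally to a count. External
#' estimates (WHO envelopes, survey coverage, prevalence atlases) are user
#' inputs — this package does not estimate them.
#'
#' @param births_per_year Total births per year (live births + stillbirths).
#' @param stillbirths Annual stillbirth count, or \code{NULL} if \code{sbr}
#'   is given.
#' @param sbr Stillbirth rate per 1000 total births, or \code{NULL} if
#'   \code{stillbirths} is given.
#' @param prop_intrapartum Fraction of stillbirths that are intrapartum.
#' @param prevalences Named list of risk-factor prevalences (fractions):
#'   \code{untreated_syphilis}, \code{diabetes}, \code{severe_hdp},
#'   \code{malaria_exposure}, \code{poverty}; \code{prolonged_pregnancy}
#'   defaults to 0.075 (the share of pregnancies progressing past term absent
#'   an induction policy).
#' @param baseline_indicators Named list of baseline coverage indicators
#'   (fractions): \code{anc4}, \code{sba}, \code{facility_delivery},
#'   \code{iptp_or_itn}; optional direct overrides for any intervention id
#'   (e.g. \code{syphilis}, \code{micronutrient}) bypass the proxy rules.
#' @param name Optional display name.
#' @return A list of class \code{"country_profile"}.
#' @export
country_profile <- function(births_per_year,
                            stillbirths = NULL, sbr = NULL,
                            prop_intrapartum,
                            prevalences = list(),
                            baseline_indicators = list(),
                            name = NA_character_) {
  if (!is.numeric(births_per_year) || births_per_year <= 0) {
    stop("births_per_year must be a positive count", call. = FALSE)
  }
  if (is.null(stillbirths) && is.null(sbr)) {
    stop("one of 'stillbirths' or 'sbr' must be supplied", call. = FALSE)
  }
  if (is.null(stillbirths)) {
    check_nonneg(sbr, "sbr")
    stillbirths <- sbr * births_per_year / 1000
  }
  check_nonneg(stillbirths, "stillbirths")
  if (stillbirths > births_per_year) {
    stop("stillbirths cannot exceed births_per_year", call. = FALSE)
  }
  check_fraction(prop_intrapartum, "prop_intrapartum")
  if (is.null(prevalences$prolonged_pregnancy)) {
    prevalences$prolonged_pregnancy <- 0.075
  }
  for (nm in names(prevalences)) {
    check_fraction(prevalences[[nm]], paste0("prevalences$", nm))
  }
  defaults <- list(anc4 = 0, sba = 0, facility_delivery = 0, iptp_or_itn = 0)
  baseline_indicators <- utils::modifyList(defaults, baseline_indicators)
  for (nm in names(baseline_indicators)) {
    check_fraction(baseline_indicators[[nm]], paste0("baseline_indicators$", nm))
  }
  if (baseline_indicators$facility_delivery > baseline_indicators$sba + 1e-12) {
    stop("baseline_indicators: facility_delivery cannot exceed sba", call. = FALSE)
  }
  structure(
    list(births_per_year = births_per_year, stillbirths = stillbirths,
         prop_intrapartum = prop_intrapartum, prevalences = prevalences,
         baseline_indicators = baseline_indicators, name = name),
    class = "country_profile"
  )
}

#' @export
print.country_profile <- function(x, ...) {
  cat(sprintf("<country_profile>%s\n",
              if (is.na(x$name)) "" else paste0(" ", x$name)))
  cat(sprintf("  births/year: %s | stillbirths: %s (SBR %.1f) | intrapartum: %.0f%%\n",
              format(x$births_per_year, big.mark = ","),
              format(round(x$stillbirths), big.mark = ","),
              sbr(x$stillbirths, x$births_per_year),
              100 * x$prop_intrapartum))
  cat("  prevalences:",
      sprintf("%s=%.3f", names(x$prevalences), unlist(x$prevalences)), "\n")
  cat("  indicators: ",
      sprintf("%s=%.2f", names(x$baseline_indicators),
              unlist(x$baseline_indicators)), "\n")
  invisible(x)
}

#' Coverage scale-up scenario
#'
#' Target coverages at \code{end_year} for any subset of intervention ids,
#' plus the childbirth indicators \code{sba} and \code{facility_delivery}
#' (from which the target delivery mix is derived). Interventions without a
#' target stay at baseline. Coverage moves from baseline to target along the
#' chosen trajectory: \code{"linear"} interpolates year by year,
#' \code{"step"} jumps to the target immediately after the base year.
#'
#' @param base_year,end_year Projection span (\code{base_year < end_year}).
#' @param targets Named list of target coverages (fractions).
#' @param trajectory \code{"linear"} or \code{"step"}.
#' @return A list of class \code{"scenario"}.
#' @export
scenario <- function(base_year, end_year, targets = list(),
                     trajectory = c("linear", "step")) {
  trajectory <- match.arg(trajectory)
  if (!(is.numeric(base_year) && is.numeric(end_year) && base_year < end_year)) {
    stop("base_year must be strictly before end_year", call. = FALSE)
  }
  for (nm in names(targets)) check_fraction(targets[[nm]], paste0("targets$", nm))
  structure(
    list(base_year = as.integer(base_year), end_year = as.integer(end_year),
         targets = targets, trajectory = trajectory),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %d -> %d (%s)\n", x$base_year, x$end_year,
              x$trajectory))
  if (length(x$targets)) {
    cat("  targets:",
        sprintf("%s=%.2f", names(x$targets), unlist(x$targets)), "\n")
  } else cat("  targets: none (baseline held)\n")
  invisible(x)
}

#' Fraction of a timing compartment's stillbirths averted by one intervention
#'
#' The core linear arithmetic: effectiveness multiplied by the change in
#' coverage multiplied by the affected fraction. With effectiveness 0.82,
#' coverage rising from 0 to 0.50 and the affected fraction confined to the
#' attributable subgroup (AF = 1 within it), 41% of attributable stillbirths
#' are averted. The result is negative when coverage falls.
#'
#' @param effectiveness Fraction reduction among the affected, in \code{[0, 1]}.
#' @param cov_base,cov_target Baseline and target coverage, in \code{[0, 1]}.
#' @param af Affected fraction, in \code{[0, 1]}.
#' @return Signed fraction of the compartment's stillbirths averted.
#' @export
averted_fraction <- function(effectiveness, cov_base, cov_target, af) {
  check_fraction(effectiveness, "effectiveness")
  check_fraction(cov_base, "cov_base")
  check_fraction(cov_target, "cov_target")
  check_fraction(af, "af")
  effectiveness * (cov_target - cov_base) * af
}

#' Combine several interventions on one timing compartment
#'
#' Single-intervention arithmetic gives each intervention an averted fraction
#' \eqn{f_i = e_i \cdot af_i \cdot \Delta c_i}. Interventions acting on the
#' same compartment combine as a multiplicative residual cascade,
#' \eqn{residual = deaths \cdot \prod_i (1 - f_i)}: order-free, never exceeds
#' a 100% reduction, and matches an individual-level model in which receipt of
#' each intervention is independent. The jointly averted total is attributed
#' to interventions in proportion to their single-intervention fractions, so
#' attributed deaths plus residual equal the input exactly.
#'
#' @param deaths Compartment envelope (count, >= 0).
#' @param terms List of terms; each a list with fields \code{effectiveness},
#'   \code{af}, \code{cov_base}, \code{cov_target} and optionally \code{id}.
#' @return List with \code{averted_by_term} (named numeric) and
#'   \code{residual}.
#' @export
compartment_cascade <- function(deaths, terms = list()) {
  check_nonneg(deaths, "deaths")
  if (!length(terms)) {
    return(list(averted_by_term = numeric(0), residual = deaths))
  }
  f <- vapply(terms, function(tm) {
    averted_fraction(tm$effectiveness, tm$cov_base, tm$cov_target, tm$af)
  }, numeric(1))
  if (any(f > 1)) {
    stop("a term's effectiveness x affected fraction x coverage change exceeds 1",
         call. = FALSE)
  }
  ids <- vapply(seq_along(terms), function(i) {
    terms[[i]]$id %||% paste0("term", i)
  }, character(1))
  residual <- deaths * prod(1 - f)
  total_averted <- deaths - residual
  if (abs(sum(f)) < 1e-15) {
    # degenerate: single-intervention fractions cancel; fall back to the
    # single-intervention amounts and spread the interaction remainder evenly
    averted <- deaths * f + (total_averted - deaths * sum(f)) / length(f)
  } else {
    averted <- total_averted * f / sum(f)
  }
  names(averted) <- ids
  list(averted_by_term = averted, residual = deaths - sum(averted))
}

# Delphi effectiveness of each childbirth-care category vs home delivery
# without a skilled attendant (home itself has effect 0).
childbirth_effects <- function(registry = load_default_interventions()) {
  c(home_no_sba = 0,
    sba_outside = registry$sba_outside$intrapartum_effect$point,
    bemoc = registry$bemoc$intrapartum_effect$point,
    cemoc = registry$cemoc$intrapartum_effect$point)
}

#' Intrapartum stillbirths averted by shifting the childbirth-care mix
#'
#' All intrapartum stillbirths are susceptible to childbirth care. Each
#' category's effectiveness (default 0.23 skilled attendance outside
#' BEmOC/CEmOC, 0.45 BEmOC, 0.75 CEmOC, relative to home delivery without a
#' skilled attendant) is applied linearly to the change in its share of
#' births: \eqn{averted = deaths \cdot \sum_c e_c (target_c - base_c)},
#' clamped to the envelope. An optional renormalised mode instead compares
#' mix-weighted relative risks, accounting for the baseline mix already being
#' reflected in the envelope; it is off by default.
#'
#' @param ip_deaths Intrapartum stillbirth envelope (count).
#' @param base_mix,target_mix \code{\link{childbirth_mix}} objects.
#' @param registry Intervention registry supplying the category effects.
#' @param renormalise Use the renormalised (relative-risk ratio) form.
#' @return List with \code{averted_by_category} (named numeric over
#'   \code{sba_outside}, \code{bemoc}, \code{cemoc}, \code{home_no_sba}) and
#'   \code{averted} (their sum, clamped to \code{[-ip_deaths, ip_deaths]}).
#' @export
childbirth_impact <- function(ip_deaths, base_mix, target_mix,
                              registry = load_default_interventions(),
                              renormalise = FALSE) {
  check_nonneg(ip_deaths, "ip_deaths")
  stopifnot(inherits(base_mix, "childbirth_mix"),
            inherits(target_mix, "childbirth_mix"))
  eff <- childbirth_effects(registry)
  delta <- unlist(target_mix)[names(eff)] - unlist(base_mix)[names(eff)]
  contrib <- ip_deaths * eff * delta
  if (renormalise) {
    s_base <- sum(unlist(base_mix)[names(eff)] * (1 - eff))
    s_target <- sum(unlist(target_mix)[names(eff)] * (1 - eff))
    total <- ip_deaths * (1 - s_target / s_base)
    # attribute the renormalised total proportionally to the linear contributions
    contrib <- if (abs(sum(contrib)) < 1e-15) {
      contrib * 0
    } else {
      total * contrib / sum(contrib)
    }
  }
  total <- sum(contrib)
  clamped <- max(-ip_deaths, min(ip_deaths, total))
  if (total != clamped && total != 0) contrib <- contrib * clamped / total
  list(averted_by_category = contrib, averted = sum(contrib))
}

# Resolve baseline coverage for every non-childbirth intervention and the
# baseline delivery mix, applying the proxy rules where the profile gives no
# direct indicator.
resolve_baseline_coverage <- function(profile,
                                      registry = load_default_interventions()) {
  ind <- profile$baseline_indicators
  mix <- childbirth_mix_from_facility(ind$facility_delivery, ind$sba)
  cov <- list()
  for (spec in registry) {
    if (spec$coverage_rule == "CHILDBIRTH_MIX") next
    direct <- ind[[spec$id]]
    cov[[spec$id]] <- if (!is.null(direct)) {
      direct
    } else {
      switch(spec$coverage_rule,
        ZERO_DEFAULT = 0,
        DIRECT = if (spec$id == "malaria") ind$iptp_or_itn else 0,
        SYPHILIS_ANC4 = syphilis_coverage_from_anc4(ind$anc4),
        ANC4_SHARE = anc_condition_coverage(ind$anc4),
        CEMOC_CAP = mix$cemoc,  # all CEmOC deliveries assumed to have access
        stop(sprintf("unknown coverage rule '%s'", spec$coverage_rule),
             call. = FALSE)
      )
    }
    if (identical(spec$cap_rule, "cemoc")) {
      cov[[spec$id]] <- induction_coverage_cap(cov[[spec$id]], mix$cemoc)
    }
  }
  list(cov = cov, mix = mix)
}

#' Run a multi-year coverage scale-up projection
#'
#' Splits the stillbirth envelope into antepartum and intrapartum compartments
#' via \code{prop_intrapartum}, resolves baseline coverages (via the proxy
#' rules where the profile lacks direct indicators), interpolates coverage
#' toward the scenario targets, and per year applies the childbirth-care mix
#' shift to the intrapartum compartment first, then the multiplicative cascade
#' of the remaining interventions to each timing compartment (syphilis and
#' malaria antepartum-only; micronutrient, balanced energy, diabetes,
#' hypertensive disorders and induction on both timings). Induction coverage
#' is capped at the CEmOC delivery share each year. The envelope is static:
#' with no coverage change the stillbirth rate is constant across projection
#' years.
#'
#' @param profile A \code{\link{country_profile}}.
#' @param scenario A \code{\link{scenario}}; targets may name any intervention
#'   id plus \code{sba} and \code{facility_delivery}.
#' @param registry Intervention registry (default
#'   \code{\link{load_default_interventions}()}).
#' @param renormalise_childbirth Use the renormalised childbirth form
#'   (see \code{\link{childbirth_impact}}).
#' @return An object of class \code{"impact_result"}: list with
#'   \code{by_intervention} (data.frame: year, intervention, timing, averted),
#'   \code{by_year} (data.frame: year, envelopes, residuals, sbr, enap_met)
#'   and \code{meta}.
#' @export
run_scenario <- function(profile, scenario,
                         registry = load_default_interventions(),
                         renormalise_childbirth = FALSE) {
  stopifnot(inherits(profile, "country_profile"), inherits(scenario, "scenario"))
  base <- resolve_baseline_coverage(profile, registry)
  known <- c(names(base$cov), "sba", "facility_delivery")
  unknown <- setdiff(names(scenario$targets), known)
  if (length(unknown)) {
    stop(sprintf("scenario targets name unknown coverage keys: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  ind <- profile$baseline_indicators
  sba_t <- scenario$targets$sba %||% ind$sba
  fac_t <- scenario$targets$facility_delivery %||% ind$facility_delivery
  target_mix <- childbirth_mix_from_facility(fac_t, sba_t)
  target_cov <- base$cov
  for (nm in intersect(names(scenario$targets), names(base$cov))) {
    target_cov[[nm]] <- scenario$targets[[nm]]
  }

  env_total <- profile$stillbirths
  env_ip <- env_total * profile$prop_intrapartum
  env_ap <- env_total - env_ip

  years <- seq(scenario$base_year, scenario$end_year)
  span <- scenario$end_year - scenario$base_year
  rows <- list(); yearly <- list()
  cascade_ids <- names(base$cov)

  for (y in years) {
    t <- if (scenario$trajectory == "step") {
      as.numeric(y > scenario$base_year)
    } else {
      (y - scenario$base_year) / span
    }
    cov_y <- lapply(cascade_ids, function(id) {
      base$cov[[id]] + t * (target_cov[[id]] - base$cov[[id]])
    })
    names(cov_y) <- cascade_ids
    mix_y <- do.call(childbirth_mix, as.list(
      (1 - t) * unlist(base$mix) + t * unlist(target_mix)))
    if ("induction" %in% cascade_ids) {
      cov_y$induction <- induction_coverage_cap(cov_y$induction, mix_y$cemoc)
    }

    # intrapartum: childbirth-care mix shift first, then the cascade of the
    # remaining interventions on its residual
    cb <- childbirth_impact(env_ip, base$mix, mix_y, registry,
                            renormalise = renormalise_childbirth)
    ip_after_cb <- env_ip - cb$averted

    mk_terms <- function(timing) {
      terms <- list()
      for (id in cascade_ids) {
        spec <- registry[[id]]
        eff <- spec[[paste0(timing, "_effect")]]
        if (is.null(eff)) next
        afr <- resolve_affected_fraction(af_for_timing(spec, timing), profile,
                                         timing)
        terms[[length(terms) + 1L]] <- list(
          id = id, effectiveness = eff$point, af = afr$value,
          cov_base = base$cov[[id]], cov_target = cov_y[[id]]
        )
      }
      terms
    }
    ap <- compartment_cascade(env_ap, mk_terms("antepartum"))
    ip <- compartment_cascade(ip_after_cb, mk_terms("intrapartum"))

    add_rows <- function(ids, averted, timing) {
      if (!length(ids)) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        year = y, intervention = ids, timing = timing, averted = averted,
        row.names = NULL
      )
    }
    cb_ids <- c("sba_outside", "bemoc", "cemoc")
    add_rows(cb_ids, unname(cb$averted_by_category[cb_ids]), "intrapartum")
    add_rows(names(ap$averted_by_term), unname(ap$averted_by_term), "antepartum")
    add_rows(names(ip$averted_by_term), unname(ip$averted_by_term), "intrapartum")

    res_ap <- ap$residual
    res_ip <- env_ip - cb$averted - sum(ip$averted_by_term)
    res_total <- res_ap + res_ip
    rate <- sbr(res_total, profile$births_per_year)
    yearly[[length(yearly) + 1L]] <- data.frame(
      year = y, antepartum_envelope = env_ap, intrapartum_envelope = env_ip,
      averted_antepartum = env_ap - res_ap, averted_intrapartum = env_ip - res_ip,
      residual_antepartum = res_ap, residual_intrapartum = res_ip,
      residual = res_total, sbr = rate, enap_met = enap_met(rate)
    )
  }

  structure(
    list(
      by_intervention = do.call(rbind, rows),
      by_year = do.call(rbind, yearly),
      meta = list(profile_name = profile$name,
                  births_per_year = profile$births_per_year,
                  base_year = scenario$base_year, end_year = scenario$end_year,
                  trajectory = scenario$trajectory,
                  renormalise_childbirth = renormalise_childbirth,
                  baseline_coverage = base$cov,
                  baseline_mix = unclass(base$mix),
                  target_mix = unclass(target_mix))
    ),
    class = "impact_result"
  )
}

#' @export
print.impact_result <- function(x, ...) {
  last <- x$by_year[nrow(x$by_year), ]
  cat(sprintf("<impact_result> %d-%d\n", x$meta$base_year, x$meta$end_year))
  cat(sprintf("  end-year averted: %s (antepartum %s, intrapartum %s)\n",
              format(round(last$averted_antepartum + last$averted_intrapartum),
                     big.mark = ","),
              format(round(last$averted_antepartum), big.mark = ","),
              format(round(last$averted_intrapartum), big.mark = ",")))
  cat(sprintf("  end-year SBR: %.1f per 1000 (ENAP <=12: %s)\n",
              last$sbr, ifelse(last$enap_met, "met", "not met")))
  invisible(x)
}

#' Stillbirth rate and the ENAP target
#'
#' @param stillbirths Stillbirth count.
#' @param total_births Total births (live + still), > 0.
#' @param rate Stillbirth rate per 1000 total births.
#' @param threshold ENAP target threshold (default 12 per 1000 by 2030).
#' @return \code{sbr}: stillbirths per 1000 total births. \code{enap_met}:
#'   whether the rate meets the Every Newborn Action Plan target.
#' @export
sbr <- function(stillbirths, total_births) {
  check_nonneg(stillbirths, "stillbirths")
  if (!is.numeric(total_births) || total_births <= 0) {
    stop("total_births must be positive", call. = FALSE)
  }
  1000 * stillbirths / total_births
}

#' @rdname sbr
#' @export
enap_met <- function(rate, threshold = 12) {
  check_nonneg(rate, "rate")
  rate <= threshold
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("%s must be non-negative and finite", what), call. = FALSE)
  }
  invisible(x)
}
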