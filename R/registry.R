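#' Effect estimate for one intervention and timing
#'
#' An effectiveness estimate expressed as a fraction reduction in stillbirths
#' among the affected fraction. Estimates sourced from relative risks carry the
#' source RR so the identity \code{point == 1 - rr} can be audited; Delphi
#' estimates are elicited directly as percentages (stored as fractions) and
#' their bounds are interquartile ranges, not confidence intervals.
#'
#' @param point Fraction reduction in \code{[0, 1]}.
#' @param lower,upper Optional bounds on the fraction reduction
#'   (\code{lower <= point <= upper}).
#' @param source_kind One of \code{"meta-analysis"}, \code{"delphi"}.
#' @param risk_measure One of \code{"RR"}, \code{"OR"}, \code{"percent"}.
#' @param rr Optional source relative risk for RR-derived estimates.
#' @return A list of class \code{"effect_estimate"}.
#' @export
effect_estimate <- function(point, lower = NA_real_, upper = NA_real_,
                            source_kind = c("meta-analysis", "delphi"),
                            risk_measure = c("RR", "OR", "percent"),
                            rr = NA_real_) {
  source_kind <- match.arg(source_kind)
  risk_measure <- match.arg(risk_measure)
  stopifnot(is.numeric(point), length(point) == 1L)
  structure(
    list(point = as.numeric(point), lower = as.numeric(lower),
         upper = as.numeric(upper), source_kind = source_kind,
         risk_measure = risk_measure, rr = as.numeric(rr)),
    class = "effect_estimate"
  )
}

# Convenience: fraction reduction implied by a relative risk and its CI.
effect_from_rr <- function(rr, ci_lower, ci_upper, risk_measure = "RR") {
  effect_estimate(point = 1 - rr, lower = 1 - ci_upper, upper = 1 - ci_lower,
                  source_kind = "meta-analysis", risk_measure = risk_measure,
                  rr = rr)
}

#' Affected-fraction rule for one intervention
#'
#' Describes how the affected fraction (the share of a timing compartment's
#' stillbirths susceptible to the intervention) is computed: \code{ALL} fixes
#' it at 1, \code{PREVALENCE_PROXY} uses the risk-factor prevalence directly
#' (no excess-risk estimate available), \code{PAF} computes a population
#' attributable fraction from prevalence and relative risk, and
#' \code{MALARIA_COMPOSITE} first converts falciparum-malaria exposure into
#' placental-malaria prevalence before the PAF step.
#'
#' @param rule One of \code{"ALL"}, \code{"PREVALENCE_PROXY"}, \code{"PAF"},
#'   \code{"MALARIA_COMPOSITE"}.
#' @param prevalence_key Name of the country-profile prevalence field supplying
#'   the exposure prevalence (absent for \code{ALL}).
#' @param relative_risk Excess stillbirth risk among the exposed (required for
#'   \code{PAF} and \code{MALARIA_COMPOSITE}).
#' @param extra Named list of rule-specific constants (for
#'   \code{MALARIA_COMPOSITE}: \code{placental_rate}, default 0.278).
#' @return A list of class \code{"af_spec"}.
#' @export
af_spec <- function(rule = c("ALL", "PREVALENCE_PROXY", "PAF", "MALARIA_COMPOSITE"),
                    prevalence_key = NA_character_, relative_risk = NA_real_,
                    extra = list()) {
  rule <- match.arg(rule)
  structure(
    list(rule = rule, prevalence_key = as.character(prevalence_key),
         relative_risk = as.numeric(relative_risk), extra = extra),
    class = "af_spec"
  )
}

#' Intervention specification
#'
#' Bundles one intervention's effectiveness per timing (antepartum /
#' intrapartum), affected-fraction rule, coverage-default rule and status.
#' At least one timing effect must be present; \code{status = "legacy"}
#' marks interventions dropped from the current model that are retained only
#' for reproducing historical scenarios.
#'
#' @param id Short slug used in scenarios and reports.
#' @param name Display name.
#' @param period One of \code{"periconceptual"}, \code{"pregnancy"},
#'   \code{"childbirth"}.
#' @param antepartum_effect,intrapartum_effect \code{\link{effect_estimate}}
#'   or \code{NULL} when the intervention does not act on that timing.
#' @param af Antepartum \code{\link{af_spec}} (also used intrapartum unless
#'   \code{af_intrapartum} is supplied).
#' @param af_intrapartum Optional distinct intrapartum \code{\link{af_spec}}.
#' @param coverage_rule Identifier of the baseline-coverage default rule:
#'   one of \code{"DIRECT"}, \code{"ZERO_DEFAULT"}, \code{"SYPHILIS_ANC4"},
#'   \code{"ANC4_SHARE"}, \code{"CEMOC_CAP"}, \code{"CHILDBIRTH_MIX"}.
#' @param cap_rule Optional coverage cap identifier (\code{"cemoc"} for
#'   induction of labour).
#' @param status \code{"current"} or \code{"legacy"}.
#' @param notes Free-text caveats carried into exported registries.
#' @return A list of class \code{"intervention_spec"}.
#' @export
intervention_spec <- function(id, name, period,
                              antepartum_effect = NULL,
                              intrapartum_effect = NULL,
                              af = af_spec("ALL"),
                              af_intrapartum = NULL,
                              coverage_rule = "DIRECT",
                              cap_rule = NA_character_,
                              status = c("current", "legacy"),
                              notes = NA_character_) {
  status <- match.arg(status)
  structure(
    list(id = id, name = name, period = period,
         antepartum_effect = antepartum_effect,
         intrapartum_effect = intrapartum_effect,
         af = af, af_intrapartum = af_intrapartum,
         coverage_rule = coverage_rule, cap_rule = as.character(cap_rule),
         status = status, notes = as.character(notes)),
    class = "intervention_spec"
  )
}

af_for_timing <- function(spec, timing) {
  if (identical(timing, "intrapartum") && !is.null(spec$af_intrapartum)) {
    spec$af_intrapartum
  } else {
    spec$af
  }
}

#' Default intervention registry
#'
#' The interventions currently modelled against the stillbirth envelope, with
#' published effectiveness estimates, affected-fraction inputs and baseline
#' coverage-proxy rules. Childbirth care is carried as three mutually exclusive
#' levels (skilled attendance outside BEmOC/CEmOC facilities, BEmOC, CEmOC),
#' giving ten current specifications for the eight interventions.
#'
#' Notes on individual entries:
#' \itemize{
#'   \item Micronutrient supplementation: the meta-analytic RR 0.92 is encoded
#'     as effectiveness 0.08; the source review rounds this to a "9% reduction"
#'     in its prose. An updated Cochrane estimate (RR 0.97, CI spanning 1)
#'     suggests the effect may be removed in future revisions; it is retained
#'     here, flagged in \code{notes}.
#'   \item Malaria prevention (ITN, with IPTp coverage accepted as a proxy)
#'     acts on antepartum stillbirths only.
#'   \item Induction for pregnancies >41 weeks uses the all-cause perinatal
#'     death RR 0.31 (the stillbirth-only estimate was underpowered); its
#'     coverage is capped at the CEmOC delivery share.
#'   \item The hypertensive-disorders exposure RR 2.1 has no published source
#'     reference and should be treated as soft.
#' }
#'
#' @param include_legacy Also return interventions removed from the current
#'   model (folic acid supplementation; fetal-growth-restriction detection).
#' @return Named list of \code{\link{intervention_spec}} objects.
#' @export
load_default_interventions <- function(include_legacy = FALSE) {
  specs <- list(
    intervention_spec(
      id = "micronutrient", name = "Multiple micronutrient supplementation",
      period = "pregnancy",
      antepartum_effect = effect_from_rr(0.92, 0.86, 0.99),
      intrapartum_effect = effect_from_rr(0.92, 0.86, 0.99),
      af = af_spec("ALL"),
      coverage_rule = "ZERO_DEFAULT",
      notes = paste("Updated Cochrane RR 0.97 (0.87-1.09) suggests no effect;",
                    "retained pending technical working group review.")
    ),
    intervention_spec(
      id = "malaria", name = "Malaria prevention with IPTp or ITN",
      period = "pregnancy",
      antepartum_effect = effect_from_rr(0.67, 0.47, 0.97),
      af = af_spec("MALARIA_COMPOSITE", prevalence_key = "malaria_exposure",
                   relative_risk = 2.19,
                   extra = list(placental_rate = 0.278)),
      coverage_rule = "DIRECT",
      notes = paste("Effectiveness is from ITN trials; placental-malaria rate",
                    "27.8% is the primigravida figure (0.208 second, 0.156",
                    "higher-order pregnancies available as overrides).")
    ),
    intervention_spec(
      id = "balanced_energy", name = "Balanced energy supplementation",
      period = "pregnancy",
      antepartum_effect = effect_from_rr(0.60, 0.39, 0.94),
      intrapartum_effect = effect_from_rr(0.60, 0.39, 0.94),
      af = af_spec("PREVALENCE_PROXY", prevalence_key = "poverty"),
      coverage_rule = "ZERO_DEFAULT",
      notes = "Poverty headcount (<$1.90/day) proxies food insecurity."
    ),
    intervention_spec(
      id = "syphilis", name = "Syphilis detection and treatment",
      period = "pregnancy",
      antepartum_effect = effect_from_rr(0.18, 0.10, 0.33),
      af = af_spec("PAF", prevalence_key = "untreated_syphilis",
                   relative_risk = 10.89),
      coverage_rule = "SYPHILIS_ANC4"
    ),
    intervention_spec(
      id = "diabetes", name = "Diabetes screening and management",
      period = "pregnancy",
      antepartum_effect = effect_estimate(0.10, -0.05, 0.30, "delphi", "percent"),
      intrapartum_effect = effect_estimate(0.10, 0.035, 0.25, "delphi", "percent"),
      af = af_spec("PAF", prevalence_key = "diabetes", relative_risk = 3.38),
      coverage_rule = "ANC4_SHARE"
    ),
    intervention_spec(
      id = "hdp", name = "Management of hypertensive disorders of pregnancy",
      period = "pregnancy",
      antepartum_effect = effect_estimate(0.20, -0.10, 0.30, "delphi", "percent"),
      intrapartum_effect = effect_estimate(0.20, 0.10, 0.40, "delphi", "percent"),
      af = af_spec("PAF", prevalence_key = "severe_hdp", relative_risk = 2.1),
      coverage_rule = "ANC4_SHARE",
      notes = "Exposure RR 2.1 has no available source reference."
    ),
    intervention_spec(
      id = "induction", name = "Induction of labour for pregnancies >41 weeks",
      period = "childbirth",
      antepartum_effect = effect_from_rr(0.31, 0.12, 0.88),
      intrapartum_effect = effect_from_rr(0.31, 0.12, 0.88),
      af = af_spec("PAF", prevalence_key = "prolonged_pregnancy",
                   relative_risk = 1.8),
      coverage_rule = "CEMOC_CAP", cap_rule = "cemoc",
      notes = paste("Effect is the all-cause perinatal death RR;",
                    "coverage capped at the CEmOC delivery share.")
    ),
    intervention_spec(
      id = "sba_outside",
      name = "Skilled attendance outside BEmOC or CEmOC facilities",
      period = "childbirth",
      intrapartum_effect = effect_from_rr(0.77, 0.69, 0.85),
      af = af_spec("ALL"),
      coverage_rule = "CHILDBIRTH_MIX"
    ),
    intervention_spec(
      id = "bemoc", name = "Childbirth care in BEmOC facility",
      period = "childbirth",
      intrapartum_effect = effect_estimate(0.45, 0.30, 0.70, "delphi", "percent"),
      af = af_spec("ALL"),
      coverage_rule = "CHILDBIRTH_MIX"
    ),
    intervention_spec(
      id = "cemoc", name = "Childbirth care in CEmOC facility",
      period = "childbirth",
      intrapartum_effect = effect_estimate(0.75, 0.50, 0.87, "delphi", "percent"),
      af = af_spec("ALL"),
      coverage_rule = "CHILDBIRTH_MIX"
    )
  )
  if (include_legacy) {
    specs <- c(specs, list(
      intervention_spec(
        id = "folic_acid", name = "Folic acid supplementation",
        period = "periconceptual",
        antepartum_effect = effect_estimate(0, source_kind = "meta-analysis"),
        intrapartum_effect = effect_estimate(0, source_kind = "meta-analysis"),
        af = af_spec("ALL"), coverage_rule = "ZERO_DEFAULT", status = "legacy",
        notes = paste("Removed Feb 2016: supplementation showed no effect on",
                      "all-cause stillbirths (RR 1.05, 0.54-2.05); no historical",
                      "effect size is published, so the estimate is null.")
      ),
      intervention_spec(
        id = "fgr_detection",
        name = "Fetal growth restriction detection and management",
        period = "pregnancy",
        antepartum_effect = effect_estimate(0.20, source_kind = "delphi",
                                            risk_measure = "percent"),
        intrapartum_effect = effect_estimate(0.20, source_kind = "delphi",
                                             risk_measure = "percent"),
        af = af_spec("ALL"), coverage_rule = "ZERO_DEFAULT", status = "legacy",
        notes = paste("Removed May 2015: screening package and effectiveness",
                      "poorly defined across settings; Delphi 20% in high-risk",
                      "pregnancies.")
      )
    ))
  }
  names(specs) <- vapply(specs, `[[`, character(1), "id")
  specs
}

#' Validate an intervention specification
#'
#' Checks the structural invariants of an \code{\link{intervention_spec}} and
#' returns human-readable descriptions of any violations (an empty character
#' vector means the spec is valid). Violations are reported, never raised, so
#' user-supplied registry overrides can be linted in bulk.
#'
#' @param spec An \code{\link{intervention_spec}}.
#' @return Character vector of violation descriptions.
#' @export
validate_spec <- function(spec) {
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)
  if (is.null(spec$antepartum_effect) && is.null(spec$intrapartum_effect)) {
    note("at least one of antepartum_effect/intrapartum_effect must be present")
  }
  for (timing in c("antepartum", "intrapartum")) {
    eff <- spec[[paste0(timing, "_effect")]]
    if (is.null(eff)) next
    if (!is.finite(eff$point) || eff$point < 0 || eff$point > 1) {
      note(sprintf("%s effect point %.4g outside [0, 1]", timing, eff$point))
    }
    if (is.finite(eff$lower) && is.finite(eff$upper)) {
      if (eff$lower > eff$point || eff$point > eff$upper) {
        note(sprintf("%s effect bounds must satisfy lower <= point <= upper",
                     timing))
      }
    }
  }
  for (af in Filter(Negate(is.null), list(spec$af, spec$af_intrapartum))) {
    needs_rr <- af$rule %in% c("PAF", "MALARIA_COMPOSITE")
    if (needs_rr && !is.finite(af$relative_risk)) {
      note(sprintf("rule %s requires relative_risk", af$rule))
    }
    if (!needs_rr && is.finite(af$relative_risk)) {
      note(sprintf("rule %s must not carry relative_risk", af$rule))
    }
    if (is.finite(af$relative_risk) && af$relative_risk <= 0) {
      note("relative_risk must be positive")
    }
    if (af$rule != "ALL" && (is.na(af$prevalence_key) ||
                             !nzchar(af$prevalence_key))) {
      note(sprintf("rule %s requires prevalence_key", af$rule))
    }
  }
  bad
}

#' @export
print.intervention_spec <- function(x, ...) {
  timings <- c(if (!is.null(x$antepartum_effect)) "antepartum",
               if (!is.null(x$intrapartum_effect)) "intrapartum")
  eff <- x$antepartum_effect %||% x$intrapartum_effect
  cat(sprintf("<intervention_spec> %s [%s]\n", x$name, x$id))
  cat(sprintf("  period: %s | status: %s | timings: %s\n",
              x$period, x$status, paste(timings, collapse = "+")))
  cat(sprintf("  effectiveness: %.2f (%s) | AF rule: %s\n",
              eff$point, eff$source_kind, x$af$rule))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export or import a registry as a structured config document
#'
#' Registries round-trip through YAML (or JSON, by file extension) so users can
#' run sensitivity variants without touching code. Fractions are decimals in
#' \code{[0, 1]}.
#'
#' @param registry Named list of \code{\link{intervention_spec}}s.
#' @param path File path ending in \code{.yaml}/\code{.yml} or \code{.json}.
#' @return \code{write_registry} returns \code{path} invisibly;
#'   \code{read_registry} returns the registry list.
#' @export
write_registry <- function(registry, path) {
  doc <- lapply(unname(registry), function(s) {
    out <- list(
      id = s$id, name = s$name, period = s$period,
      coverage_rule = s$coverage_rule, status = s$status
    )
    for (timing in c("antepartum", "intrapartum")) {
      eff <- s[[paste0(timing, "_effect")]]
      if (!is.null(eff)) {
        out[[paste0(timing, "_effect")]] <-
          drop_na_fields(eff[c("point", "lower", "upper", "source_kind",
                               "risk_measure", "rr")])
      }
    }
    out$af <- drop_na_fields(s$af[c("rule", "prevalence_key", "relative_risk")])
    if (length(s$af$extra)) out$af$extra <- s$af$extra
    if (!is.null(s$af_intrapartum)) {
      out$af_intrapartum <- drop_na_fields(
        s$af_intrapartum[c("rule", "prevalence_key", "relative_risk")])
      if (length(s$af_intrapartum$extra))
        out$af_intrapartum$extra <- s$af_intrapartum$extra
    }
    if (!is.na(s$cap_rule)) out$cap_rule <- s$cap_rule
    if (!is.na(s$notes)) out$notes <- s$notes
    out
  })
  write_config(list(interventions = doc), path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  doc <- read_config(path)
  if (is.null(doc$interventions)) {
    stop("registry document must contain an 'interventions' list", call. = FALSE)
  }
  specs <- lapply(doc$interventions, function(s) {
    mk_eff <- function(e) {
      if (is.null(e)) return(NULL)
      effect_estimate(point = e$point, lower = e$lower %||% NA_real_,
                      upper = e$upper %||% NA_real_,
                      source_kind = e$source_kind %||% "meta-analysis",
                      risk_measure = e$risk_measure %||% "RR",
                      rr = e$rr %||% NA_real_)
    }
    mk_af <- function(a) {
      if (is.null(a)) return(NULL)
      af_spec(rule = a$rule, prevalence_key = a$prevalence_key %||% NA_character_,
              relative_risk = a$relative_risk %||% NA_real_,
              extra = a$extra %||% list())
    }
    spec <- intervention_spec(
      id = s$id, name = s$name, period = s$period,
      antepartum_effect = mk_eff(s$antepartum_effect),
      intrapartum_effect = mk_eff(s$intrapartum_effect),
      af = mk_af(s$af), af_intrapartum = mk_af(s$af_intrapartum),
      coverage_rule = s$coverage_rule %||% "DIRECT",
      cap_rule = s$cap_rule %||% NA_character_,
      status = s$status %||% "current",
      notes = s$notes %||% NA_character_
    )
    bad <- validate_spec(spec)
    if (length(bad)) {
      stop(sprintf("invalid intervention '%s': %s", s$id,
                   paste(bad, collapse = "; ")), call. = FALSE)
    }
    spec
  })
  names(specs) <- vapply(specs, `[[`, character(1), "id")
  specs
}

drop_na_fields <- function(x) {
  Filter(function(v) !(length(v) == 1L && is.na(v)), x)
}
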