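test_that("default registry carries the ten current intervention specs", {
  reg <- load_default_interventions()
  expect_setequal(
    names(reg),
    c("micronutrient", "malaria", "balanced_energy", "syphilis", "diabetes",
      "hdp", "induction", "sba_outside", "bemoc", "cemoc")
  )
  expect_true(all(vapply(reg, `[[`, character(1), "status") == "current"))
  expect_length(unlist(lapply(reg, validate_spec)), 0)
})

test_that("effectiveness points match the published estimates", {
  reg <- load_default_interventions()

  expect_equal(reg$syphilis$antepartum_effect$point, 0.82)
  expect_null(reg$syphilis$intrapartum_effect)

  expect_equal(reg$cemoc$intrapartum_effect$point, 0.75)
  expect_identical(reg$cemoc$intrapartum_effect$source_kind, "delphi")
  expect_identical(reg$cemoc$af$rule, "ALL")

  expect_equal(reg$balanced_energy$antepartum_effect$point, 0.40)
  expect_equal(reg$balanced_energy$intrapartum_effect$point, 0.40)
  expect_identical(reg$balanced_energy$af$rule, "PREVALENCE_PROXY")
  expect_identical(reg$balanced_energy$af$prevalence_key, "poverty")

  expect_equal(reg$micronutrient$antepartum_effect$point, 0.08)
  expect_equal(reg$malaria$antepartum_effect$point, 0.33)
  expect_equal(reg$induction$antepartum_effect$point, 0.69)
  expect_equal(reg$diabetes$antepartum_effect$point, 0.10)
  expect_equal(reg$hdp$antepartum_effect$point, 0.20)
  expect_equal(reg$sba_outside$intrapartum_effect$point, 0.23)
  expect_equal(reg$bemoc$intrapartum_effect$point, 0.45)

  # every RR-sourced point is exactly one minus its source RR
  for (spec in reg) {
    for (timing in c("antepartum_effect", "intrapartum_effect")) {
      eff <- spec[[timing]]
      if (is.null(eff) || !is.finite(eff$rr)) next
      expect_equal(eff$point, 1 - eff$rr, tolerance = 1e-12)
      expect_true(eff$point > 0 && eff$point <= 1)
    }
  }
})

test_that("timing applicability matches the model's antepartum/intrapartum marks", {
  reg <- load_default_interventions()
  has <- function(id, timing) !is.null(reg[[id]][[paste0(timing, "_effect")]])
  both <- c("micronutrient", "balanced_energy", "diabetes", "hdp", "induction")
  for (id in both) {
    expect_true(has(id, "antepartum"), label = paste(id, "antepartum"))
    expect_true(has(id, "intrapartum"), label = paste(id, "intrapartum"))
  }
  for (id in c("syphilis", "malaria")) {
    expect_true(has(id, "antepartum"))
    expect_false(has(id, "intrapartum"))
  }
  for (id in c("sba_outside", "bemoc", "cemoc")) {
    expect_false(has(id, "antepartum"))
    expect_true(has(id, "intrapartum"))
  }
})

test_that("legacy interventions only load on request and are marked legacy", {
  expect_false("fgr_detection" %in% names(load_default_interventions()))
  reg <- load_default_interventions(include_legacy = TRUE)
  expect_true(all(c("folic_acid", "fgr_detection") %in% names(reg)))
  expect_identical(reg$fgr_detection$status, "legacy")
  expect_equal(reg$fgr_detection$antepartum_effect$point, 0.20)
})

test_that("validate_spec reports violations instead of raising", {
  reg <- load_default_interventions()
  expect_identical(validate_spec(reg$syphilis), character(0))

  bad_point <- reg$syphilis
  bad_point$antepartum_effect$point <- 1.3
  v <- validate_spec(bad_point)
  expect_true(any(grepl("outside \\[0, 1\\]", v)))

  no_rr <- intervention_spec(
    id = "x", name = "x", period = "pregnancy",
    antepartum_effect = effect_estimate(0.5),
    af = af_spec("PAF", prevalence_key = "diabetes")
  )
  expect_match(validate_spec(no_rr), "relative_risk")

  no_effect <- intervention_spec(id = "x", name = "x", period = "pregnancy")
  expect_match(validate_spec(no_effect), "at least one")
})

test_that("registries round-trip through YAML and JSON config documents", {
  reg <- load_default_interventions(include_legacy = TRUE)
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_registry(reg, path)
    back <- read_registry(path)
    expect_setequal(names(back), names(reg))
    for (id in names(reg)) {
      expect_equal(back[[id]][c("id", "period", "coverage_rule", "status")],
                   reg[[id]][c("id", "period", "coverage_rule", "status")])
      for (t in c("antepartum_effect", "intrapartum_effect")) {
        if (is.null(reg[[id]][[t]])) {
          expect_null(back[[id]][[t]])
        } else {
          expect_equal(back[[id]][[t]]$point, reg[[id]][[t]]$point)
        }
      }
      expect_equal(back[[id]]$af$rule, reg[[id]]$af$rule)
      expect_equal(back[[id]]$af$relative_risk, reg[[id]]$af$relative_risk)
    }
    unlink(path)
  }
})
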