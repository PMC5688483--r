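test_that("averted fraction is effectiveness x coverage change x affected fraction", {
  expect_equal(averted_fraction(0.82, 0, 0.50, 1.0), 0.41)
  expect_equal(averted_fraction(0.40, 0, 0.50, 0.20), 0.04)
  expect_identical(averted_fraction(0.9, 0.3, 0.3, 0.5), 0)
  expect_lt(averted_fraction(0.5, 0.6, 0.2, 1), 0)
  expect_error(averted_fraction(1.2, 0, 1, 1), "fraction")
})

test_that("compartment cascade conserves deaths and matches worked arithmetic", {
  one <- compartment_cascade(1000, list(
    list(id = "syphilis", effectiveness = 0.82, af = 1.0,
         cov_base = 0, cov_target = 0.5)))
  expect_equal(unname(one$averted_by_term), 410)
  expect_equal(one$residual, 590)

  none <- compartment_cascade(1000, list())
  expect_identical(none$residual, 1000)
  expect_length(none$averted_by_term, 0)

  two <- compartment_cascade(1000, list(
    list(effectiveness = 0.5, af = 0.4, cov_base = 0, cov_target = 0.5),
    list(effectiveness = 0.25, af = 0.8, cov_base = 0, cov_target = 0.5)))
  expect_equal(two$residual, 1000 * 0.9 * 0.9)

  expect_error(
    compartment_cascade(10, list(
      list(effectiveness = 1, af = 1, cov_base = 0, cov_target = 1),
      list(effectiveness = 1, af = 1, cov_base = 0, cov_target = 1))),
    NA)  # f = 1 each is allowed: residual 0
  expect_error(
    compartment_cascade(10, list(
      list(effectiveness = 1.0, af = 1.5, cov_base = 0, cov_target = 1))),
    "fraction")
})

test_that("cascade is order-invariant and exactly conservative over random cases", {
  set.seed(21)
  for (i in 1:200) {
    k <- sample(1:6, 1)
    terms <- lapply(seq_len(k), function(j) {
      list(id = paste0("i", j), effectiveness = runif(1), af = runif(1),
           cov_base = runif(1), cov_target = runif(1))
    })
    deaths <- runif(1, 0, 1e5)
    res <- compartment_cascade(deaths, terms)
    expect_equal(sum(res$averted_by_term) + res$residual, deaths,
                 tolerance = 1e-12)
    perm <- sample(k)
    res2 <- compartment_cascade(deaths, terms[perm])
    expect_equal(res2$residual, res$residual, tolerance = 1e-9)
    expect_equal(res2$averted_by_term[paste0("i", seq_len(k))],
                 res$averted_by_term[paste0("i", seq_len(k))],
                 tolerance = 1e-9)
  }
})

test_that("childbirth impact applies category effects to mix shifts", {
  all_home <- childbirth_mix(1, 0, 0, 0)
  expect_identical(childbirth_impact(1000, all_home, all_home)$averted, 0)
  expect_equal(
    childbirth_impact(1000, all_home, childbirth_mix(0, 0, 0, 1))$averted, 750)
  expect_equal(
    childbirth_impact(1000, all_home, childbirth_mix(0, 0, 1, 0))$averted, 450)
  expect_equal(
    childbirth_impact(1000, all_home, childbirth_mix(0, 1, 0, 0))$averted, 230)
  # symmetric increase in deaths when care coverage falls
  expect_equal(
    childbirth_impact(1000, childbirth_mix(0, 0, 0, 1), all_home)$averted, -750)
})

test_that("a zero-change scenario averts nothing and holds the rate static", {
  prof <- generate_profile_fixture(5, "transition")
  res <- run_scenario(prof, scenario(2025, 2030))
  expect_true(all(abs(res$by_intervention$averted) < 1e-9))
  expect_equal(var(res$by_year$sbr), 0)
  expect_equal(res$by_year$residual,
               rep(prof$stillbirths, nrow(res$by_year)), tolerance = 1e-9)
})

test_that("the syphilis worked example propagates through a full projection", {
  prof <- syphilis_example_profile(attributable = 1000)
  res <- run_scenario(prof, scenario(2025, 2030,
                                     targets = list(syphilis = 0.5)))
  last <- res$by_intervention[res$by_intervention$year == 2030 &
                              res$by_intervention$intervention == "syphilis", ]
  expect_equal(last$averted, 410, tolerance = 1e-9)
  expect_identical(last$timing, "antepartum")
  # every other intervention is untouched
  others <- res$by_intervention[res$by_intervention$intervention != "syphilis", ]
  expect_true(all(abs(others$averted) < 1e-9))
})

test_that("projection conserves the envelope per timing every year", {
  prof <- generate_profile_fixture(9, "high-burden")
  scn <- scenario(2025, 2030, targets = list(
    syphilis = 0.8, malaria = 0.7, micronutrient = 0.5, balanced_energy = 0.4,
    diabetes = 0.3, hdp = 0.3, induction = 0.5, sba = 0.95,
    facility_delivery = 0.9))
  res <- run_scenario(prof, scn)
  for (y in unique(res$by_year$year)) {
    yr <- res$by_year[res$by_year$year == y, ]
    bi <- res$by_intervention[res$by_intervention$year == y, ]
    expect_equal(sum(bi$averted[bi$timing == "antepartum"]) +
                   yr$residual_antepartum, yr$antepartum_envelope,
                 tolerance = 1e-9)
    expect_equal(sum(bi$averted[bi$timing == "intrapartum"]) +
                   yr$residual_intrapartum, yr$intrapartum_envelope,
                 tolerance = 1e-9)
  }
  # averted grows along the linear trajectory
  expect_true(all(diff(res$by_year$residual) < 0))
})

test_that("raising any single target coverage never increases residual deaths", {
  prof <- generate_profile_fixture(13, "high-burden")
  base_res <- run_scenario(prof, scenario(2025, 2030))
  base_residual <- base_res$by_year$residual[6]
  targets <- list(syphilis = 0.9, malaria = 0.8, micronutrient = 0.6,
                  balanced_energy = 0.6, diabetes = 0.5, hdp = 0.5,
                  induction = 0.9, sba = 0.95)
  for (nm in names(targets)) {
    res <- run_scenario(prof, scenario(2025, 2030,
                                       targets = targets[nm]))
    expect_lte(res$by_year$residual[6], base_residual + 1e-9, label = nm)
  }
})

test_that("step trajectories jump to the target immediately after base year", {
  prof <- syphilis_example_profile()
  res <- run_scenario(prof, scenario(2025, 2030,
                                     targets = list(syphilis = 0.5),
                                     trajectory = "step"))
  sy <- res$by_intervention[res$by_intervention$intervention == "syphilis", ]
  expect_equal(sy$averted[sy$year == 2025], 0)
  expect_equal(sy$averted[sy$year == 2026], 410, tolerance = 1e-9)
  expect_equal(sy$averted[sy$year == 2030], 410, tolerance = 1e-9)
})

test_that("unknown scenario targets are a configuration error", {
  prof <- generate_profile_fixture(3, "transition")
  expect_error(
    run_scenario(prof, scenario(2025, 2030, targets = list(aspirin = 0.5))),
    "aspirin")
})

test_that("stillbirth rate and ENAP status", {
  expect_identical(sbr(12, 1000), 12)
  expect_true(enap_met(sbr(12, 1000)))
  expect_identical(sbr(0, 1000), 0)
  expect_true(enap_met(0))
  expect_identical(sbr(26, 1000), 26)
  expect_false(enap_met(26))
  expect_error(sbr(10, 0), "positive")
})
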