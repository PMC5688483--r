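no_risk_profile <- function() {
  country_profile(
    births_per_year = 1e6, sbr = 20, prop_intrapartum = 0.3,
    prevalences = list(untreated_syphilis = 0, diabetes = 0, severe_hdp = 0,
                       malaria_exposure = 0, poverty = 0,
                       prolonged_pregnancy = 0)
  )
}

test_that("identical sim configs give identical counts; global RNG is untouched", {
  prof <- generate_profile_fixture(2, "high-burden")
  cfg <- sim_config(5e4, seed = 31, baseline_risk_ap = 0.01,
                    baseline_risk_ip = 0.005, profile = prof,
                    coverage = list(syphilis = 0.5))
  set.seed(1234)
  before <- runif(1)
  set.seed(1234)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$strata, b$strata)
  expect_identical(runif(1), before)
})

test_that("with no exposures or coverage the death count is binomial", {
  cfg <- sim_config(1e6, seed = 8, baseline_risk_ap = 0.01,
                    baseline_risk_ip = 0, profile = no_risk_profile())
  counts <- simulate_cohort(cfg)$counts
  expect_lt(abs(counts[["antepartum_sb"]] - 1e4),
            3 * sqrt(1e6 * 0.01 * 0.99))
  expect_identical(counts[["intrapartum_sb"]], 0L)
  expect_identical(sum(counts), 1000000L)
})

test_that("simulated exposure strata recover the input relative risks", {
  prof <- no_risk_profile()
  prof$prevalences$untreated_syphilis <- 0.08
  prof$prevalences$diabetes <- 0.10
  cfg <- sim_config(1e6, seed = 77, baseline_risk_ap = 0.01,
                    baseline_risk_ip = 0.005, profile = prof)
  st <- simulate_cohort(cfg)$strata
  for (row in list(c("untreated_syphilis", 10.89), c("diabetes", 3.38))) {
    s <- st[st$factor == row[1], ]
    rate <- s$antepartum_sb / s$n
    rr_hat <- rate[s$exposed] / rate[!s$exposed]
    rr <- as.numeric(row[2])
    # delta-method SE of the log rate ratio
    se_log <- sqrt(1 / s$antepartum_sb[s$exposed] +
                   1 / s$antepartum_sb[!s$exposed])
    expect_lt(abs(log(rr_hat) - log(rr)), 3 * se_log, label = row[1])
  }
})

test_that("the measured attributable fraction matches the closed-form PAF", {
  prof <- no_risk_profile()
  prof$prevalences$untreated_syphilis <- 0.05
  cfg <- sim_config(1e6, seed = 55, baseline_risk_ap = 0.01,
                    baseline_risk_ip = 0, profile = prof)
  st <- simulate_cohort(cfg)$strata
  s <- st[st$factor == "untreated_syphilis", ]
  total <- sum(s$antepartum_sb)
  unexposed_rate <- s$antepartum_sb[!s$exposed] / s$n[!s$exposed]
  af_hat <- (s$antepartum_sb[s$exposed] -
               s$n[s$exposed] * unexposed_rate) / total
  expect_lt(abs(af_hat - paf(0.05, 10.89)), 3 / sqrt(total))
})

test_that("scaling syphilis coverage to 50% averts 41% of attributable deaths", {
  prof <- no_risk_profile()
  prof$prevalences$untreated_syphilis <- 0.05
  measure_attributable <- function(coverage, seed) {
    cfg <- sim_config(1e6, seed = seed, baseline_risk_ap = 0.02,
                      baseline_risk_ip = 0, profile = prof,
                      coverage = coverage)
    s <- simulate_cohort(cfg)$strata
    s <- s[s$factor == "untreated_syphilis", ]
    unexposed_rate <- s$antepartum_sb[!s$exposed] / s$n[!s$exposed]
    s$antepartum_sb[s$exposed] - s$n[s$exposed] * unexposed_rate
  }
  att0 <- measure_attributable(list(), seed = 10)
  att1 <- measure_attributable(list(syphilis = 0.5), seed = 20)
  reduction <- 1 - att1 / att0
  se <- sqrt(att1 + (att1 / att0)^2 * att0) / att0
  expect_lt(abs(reduction - 0.41), 3 * se)
})

test_that("synthetic profiles are deterministic per seed and valid", {
  for (arch in c("high-burden", "transition", "low-burden")) {
    p1 <- generate_profile_fixture(42, arch)
    p2 <- generate_profile_fixture(42, arch)
    expect_identical(p1, p2)
    expect_s3_class(p1, "country_profile")  # constructor enforces invariants
    expect_true(p1$baseline_indicators$facility_delivery <=
                  p1$baseline_indicators$sba)
  }
  expect_false(identical(generate_profile_fixture(1, "transition"),
                         generate_profile_fixture(2, "transition")))
})

test_that("high-burden fixtures miss the ENAP target by construction", {
  for (seed in 1:10) {
    p <- generate_profile_fixture(seed, "high-burden")
    expect_false(enap_met(sbr(p$stillbirths, p$births_per_year)))
  }
})

test_that("single-intervention engine predictions sit within 3 SE of the microsim", {
  prof <- generate_profile_fixture(6, "high-burden")
  ag <- engine_microsim_agreement(prof, n = 2e5, seed = 17)
  expect_true(all(is.finite(ag$z)))
  expect_lt(max(abs(ag$z)), 3)
  # every current non-childbirth intervention plus the three care levels appear
  expect_setequal(unique(ag$intervention),
                  c("micronutrient", "malaria", "balanced_energy", "syphilis",
                    "diabetes", "hdp", "induction", "sba_outside", "bemoc",
                    "cemoc"))
})
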