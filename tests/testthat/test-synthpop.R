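# Generator: census sampling, event simulation, the two coding regimes, and
# registry degradation with retained truth.

test_that("census generation honours size, uniqueness and determinism", {
  pc <- population_config(1000, seed = 7)
  cen <- generate_census(pc)
  expect_equal(nrow(cen), 1000)
  expect_equal(length(unique(cen$person_id)), 1000)
  expect_true(all(cen$birth_date <= cen$census_date))
  expect_equal(cen$region, unname(canton_region_map()[cen$canton]))
  cen2 <- generate_census(population_config(1000, seed = 7))
  expect_identical(cen, cen2)
  cen3 <- generate_census(population_config(1000, seed = 8))
  expect_false(identical(cen$birth_date, cen3$birth_date))
})

test_that("degenerate or invalid population configurations are rejected", {
  expect_error(population_config(0), "positive integer")
  expect_error(population_config(100, marginals = list(sex = c(a = .6,
                                                               b = .5))),
               "sum to 1")
  expect_error(population_config(100, marginals = list(sex = c(.5, .5))),
               "named")
})

test_that("sampled sex proportion matches the marginal within 3 SE", {
  n <- 50000
  pc <- population_config(n, marginals = list(
    sex = c(female = .51, male = .49)), seed = 1)
  cen <- generate_census(pc)
  phat <- mean(cen$sex == "female")
  se <- sqrt(.51 * .49 / n)
  expect_lt(abs(phat - .51), 3 * se)
})

test_that("null hazards produce no events; constant hazard matches the exponential count", {
  pc <- population_config(10000, census_date = as.Date("2000-12-05"),
                          age_range = c(30, 60), seed = 3)
  cen <- generate_census(pc)
  zero <- copy(default_hazard_table())[, rate := 0]
  hz0 <- hazard_config(hazard_table = zero, log_linear_trend = NULL,
                       mention_prob = NULL, covariate_log_hr = list(),
                       emigration_hazard = setNames(
                         rep(0, 10), age_group_labels(default_age_breaks())),
                       seed = 4)
  sim0 <- simulate_followup(cen, hz0, as.Date("2001-12-05"))
  expect_equal(nrow(sim0$deaths), 0)
  expect_equal(nrow(sim0$emigrations), 0)

  # single cause, lambda = 0.1 / yr, one-year window
  one <- copy(zero)[cause == "other", rate := 0.1]
  hz1 <- hazard_config(hazard_table = one, log_linear_trend = NULL,
                       mention_prob = NULL, covariate_log_hr = list(),
                       emigration_hazard = setNames(
                         rep(0, 10), age_group_labels(default_age_breaks())),
                       seed = 5)
  sim1 <- simulate_followup(cen, hz1, as.Date("2001-12-05"))
  p <- 1 - exp(-0.1)
  expected <- 10000 * p
  se <- sqrt(10000 * p * (1 - p))
  expect_lt(abs(nrow(sim1$deaths) - expected), 3 * se)
  expect_true(all(sim1$deaths$death_date > as.Date("2000-12-05")))
  expect_true(all(sim1$deaths$death_date <= as.Date("2001-12-05")))
  expect_equal(anyDuplicated(sim1$deaths$person_id), 0)

  # two equal causes split deaths evenly
  two <- copy(zero)[cause %in% c("other", "cardiovascular"), rate := 0.05]
  hz2 <- hazard_config(hazard_table = two, log_linear_trend = NULL,
                       mention_prob = NULL, covariate_log_hr = list(),
                       emigration_hazard = setNames(
                         rep(0, 10), age_group_labels(default_age_breaks())),
                       seed = 6)
  sim2 <- simulate_followup(cen, hz2, as.Date("2001-12-05"))
  share <- mean(sim2$deaths$underlying_cause == "other")
  se2 <- sqrt(.25 / nrow(sim2$deaths))
  expect_lt(abs(share - .5), 3 * se2)

  expect_error(simulate_followup(cen, hz1, as.Date("2000-12-05")),
               "after the census date")
})

test_that("the pre-1995 coder promotes mentioned priority causes; the post-1995 coder does not", {
  # elderly woman dying of cardiovascular disease with breast cancer mentioned
  expect_equal(assign_official_cause(as.Date("1993-05-01"), "cardiovascular",
                                     "cardiovascular;breast"), "breast")
  expect_equal(assign_official_cause(as.Date("1996-05-01"), "cardiovascular",
                                     "cardiovascular;breast"),
               "cardiovascular")
  expect_equal(assign_official_cause(as.Date("1993-05-01"), "cardiovascular",
                                     "cardiovascular"), "cardiovascular")
  # external causes outrank cancer in the priority list
  expect_equal(assign_official_cause(as.Date("1993-05-01"), "suicide",
                                     "suicide;breast"), "suicide")
  expect_equal(assign_official_cause(as.Date("1994-05-01"), "other",
                                     "other;suicide;breast"), "suicide")
  # within the same priority group the underlying cause is kept
  expect_equal(assign_official_cause(as.Date("1993-05-01"), "other_cancer",
                                     "other_cancer;breast"), "other_cancer")
  expect_error(assign_official_cause(as.Date("1993-05-01"), "other", ""),
               "non-empty")
  expect_error(assign_official_cause(as.Date("1993-05-01"), "other",
                                     "breast"), "underlying")
})

test_that("registry degradation respects stratum probabilities and conserves records", {
  run <- make_small_run(n = 6000, seed = 21)
  deaths <- run$deaths

  uc0 <- unlink_config(unlink_prob = 0, seed = 1)
  r0 <- degrade_to_registry(deaths, uc0)
  expect_equal(nrow(r0), nrow(deaths))
  expect_true(all(r0$linked))
  expect_identical(sort(r0$person_id), sort(deaths$person_id))
  m <- match(r0$truth_person_id, deaths$person_id)
  expect_identical(r0$birth_date, deaths$birth_date[m])
  expect_identical(r0$canton, deaths$canton[m])

  uc1 <- unlink_config(unlink_prob = 1, seed = 1)
  r1 <- degrade_to_registry(deaths, uc1)
  expect_true(all(!r1$linked))
  expect_true(all(is.na(r1$person_id)))
  expect_identical(r1$truth_person_id[order(r1$certificate_id)],
                   r0$truth_person_id[order(r0$certificate_id)])

  # nationality-stratified probabilities recovered within 3 binomial SE
  tab <- copy(default_unlink_table())
  tab[, prob := ifelse(nationality == "non-Swiss", 0.12, 0.047)]
  ucs <- unlink_config(unlink_prob = tab, seed = 2)
  rs <- degrade_to_registry(deaths, ucs)
  truth_nat <- deaths$nationality[match(rs$truth_person_id,
                                        deaths$person_id)]
  for (nat in c("Swiss", "non-Swiss")) {
    p <- if (nat == "non-Swiss") 0.12 else 0.047
    k <- truth_nat == nat
    se <- sqrt(p * (1 - p) / sum(k))
    expect_lt(abs(mean(!rs$linked[k]) - p), 3 * se)
  }

  rs2 <- degrade_to_registry(deaths, ucs)
  expect_identical(rs, rs2)
})

test_that("mention-driven coding creates a downward step of the analytic size", {
  # elderly female cohort: official breast-cancer rate is inflated before the
  # switch and equals the underlying rate after
  pc <- population_config(30000, census_date = as.Date("1990-12-05"),
                          marginals = list(sex = c(female = 1, male = 0)),
                          age_range = c(80, 92), seed = 31)
  cen <- generate_census(pc)
  hz <- hazard_config(log_linear_trend = NULL, covariate_log_hr = list(),
                      seed = 32)
  sim <- simulate_followup(cen, hz, as.Date("1999-12-31"))
  d <- sim$deaths[attained_age(birth_date, death_date) >= 85]
  pre <- d[death_date < as.Date("1995-01-01")]
  post <- d[death_date >= as.Date("1995-01-01")]
  expect_gt(sum(pre$official_cause == "breast"),
            sum(pre$underlying_cause == "breast"))
  expect_equal(post$official_cause, post$underlying_cause)
  # observed inflation consistent with the configured factor (0.80 at 85+)
  f_true <- coding_step_factor(hz, "breast", "female", "85+")
  expect_equal(f_true, 0.80, tolerance = 1e-12)
  ratio <- sum(pre$underlying_cause == "breast") /
    sum(pre$official_cause == "breast")
  se_ratio <- ratio * sqrt(1 / sum(pre$underlying_cause == "breast"))
  expect_lt(abs(ratio - f_true), 3 * se_ratio)
})

test_that("mention calibration inverts the analytic factor", {
  hz0 <- hazard_config(mention_prob = NULL)
  m <- mention_prob_for_factor(hz0, "prostate", "male", "85+", 0.9)
  hz1 <- hazard_config(mention_prob = data.table(
    cause = "prostate", sex = "male", age_group = "85+", prob = m))
  expect_equal(coding_step_factor(hz1, "prostate", "male", "85+"), 0.9,
               tolerance = 1e-12)
  # causes outside the priority groups are never inflated
  expect_equal(coding_step_factor(hz1, "cardiovascular", "male", "85+"), 1)
})

test_that("midyear population counts persons alive and present on 1 July", {
  cen <- data.table(
    person_id = c("a", "b", "c", "d"), sex = c("female", "female", "male",
                                               "male"),
    birth_date = as.IDate(c("1920-06-30", "1920-07-02", "1950-01-01",
                            "1950-01-01")),
    census_date = as.IDate("1990-12-05"))
  deaths <- data.table(person_id = "a", death_date = as.IDate("1991-06-30"))
  emig <- data.table(person_id = "c",
                     emigration_date = as.IDate("1991-07-01"))
  my <- midyear_population(cen, deaths, emig, 1991:1992)
  # a died before 1 Jul 1991; c emigrates exactly on 1 Jul (still counted)
  expect_equal(my[year == 1991 & sex == "female", population], 1L)
  expect_equal(sum(my[year == 1991 & sex == "male", population]), 2L)
  expect_equal(sum(my[year == 1992 & sex == "male", population]), 1L)
  # b turns 71 on 2 Jul 1991: counted at attained age 70 on 1 July
  expect_equal(my[year == 1991 & sex == "female", age_group], "65-74")
})

test_that("synthetic tables round-trip through the CSV writers", {
  run <- make_small_run(n = 1500, seed = 41)
  dir <- tempfile("synthcsv")
  paths <- write_synthetic_data(dir, run$census, run$deaths,
                                run$emigrations, run$registry)
  expect_true(all(file.exists(paths)))
  reg2 <- data.table::fread(file.path(dir, "registry.csv"))
  expect_false("truth_person_id" %in% names(reg2))
  expect_equal(nrow(reg2), nrow(run$registry))
  truth <- data.table::fread(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), nrow(run$registry))
  unlink(dir, recursive = TRUE)
})
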