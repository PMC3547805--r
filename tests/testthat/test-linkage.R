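# Two-step allocation rules: marital plausibility, impossible matches,
# candidate search, person-exclusive allocation and the summary arithmetic.

test_that("marital transitions follow the plausibility table", {
  expect_true(plausible_marital_transition("married", "widowed"))
  expect_true(plausible_marital_transition("single", "single"))
  expect_false(plausible_marital_transition("widowed", "single"))
  expect_false(plausible_marital_transition("divorced", "single"))
  expect_true(all(plausible_marital_transition(
    c("single", "married", "widowed", "divorced"),
    c("single", "married", "widowed", "divorced"))))
  expect_error(plausible_marital_transition("engaged", "married"),
               "unknown marital status")
})

test_that("sex-specific causes cannot cross sexes", {
  expect_false(sex_cause_compatible("female", "prostate"))
  expect_false(sex_cause_compatible("female", "C61"))
  expect_true(sex_cause_compatible("male", "C61"))
  expect_false(sex_cause_compatible("male", "breast"))
  expect_true(sex_cause_compatible("female", "cardiovascular"))
  expect_error(sex_cause_compatible("female", "dropsy"), "unknown cause")
})

make_person <- function(id, sex = "female", bd = "1920-01-01",
                        canton = "BE", nat = "Swiss", ms = "married") {
  data.table(person_id = id, sex = sex, birth_date = as.IDate(bd),
             canton = canton, region = canton_region_map()[canton],
             nationality = nat, marital_status = ms)
}

test_that("candidate search applies the step criteria field by field", {
  cen <- rbind(make_person("p1"),
               make_person("p2", bd = "1920-03-15"),
               make_person("p3", bd = "1920-12-01"),
               make_person("p4", sex = "male"),
               make_person("p5", canton = "FR"),
               make_person("p6", nat = "non-Swiss"),
               make_person("p7", ms = "widowed"))
  cert <- list(sex = "female", birth_date = as.IDate("1920-01-01"),
               canton = "BE", region = "Espace Mittelland",
               nationality = "Swiss", marital_status = "married",
               official_cause = "cardiovascular")
  c1 <- find_candidates(cert, cen, match_criteria(1))
  # p2 within 92 days; p7 widowed at census, married at death (remarriage,
  # plausible); p5/p6 fail canton/nationality; p3 outside tolerance; p4
  # wrong sex
  expect_setequal(c1, c("p1", "p2", "p7"))
  c2 <- find_candidates(cert, cen, match_criteria(2))
  # region-level: p5 (FR, same region) returns; p3 within a year; p7 ignored
  # marital; p6 ignored nationality
  expect_setequal(c2, c("p1", "p2", "p3", "p5", "p6", "p7"))

  # certificate 200 days away from everyone fails step 1
  cert2 <- utils::modifyList(cert, list(birth_date = as.IDate("1920-07-19")))
  expect_length(find_candidates(cert2, cen[1:2], match_criteria(1)), 0)

  # sex-specific cause removes all candidates of the incompatible sex
  cert3 <- utils::modifyList(cert, list(official_cause = "prostate"))
  expect_length(find_candidates(cert3, cen, match_criteria(1)), 0)
})

make_cert <- function(id, pid = NA_character_, linked = FALSE,
                      sex = "female", bd = "1920-01-01",
                      dd = "1995-06-01", canton = "BE", nat = "Swiss",
                      ms = "married", cause = "cardiovascular") {
  data.table(certificate_id = id, sex = sex, birth_date = as.IDate(bd),
             death_date = as.IDate(dd), canton = canton,
             region = canton_region_map()[canton], nationality = nat,
             marital_status = ms, official_cause = cause, linked = linked,
             person_id = pid, truth_person_id = pid)
}

test_that("allocation is person-exclusive, deterministic and validates input", {
  cen <- rbind(make_person("p1"), make_person("p2", bd = "1980-01-01"))
  # no unlinked certificates at all
  r0 <- allocate_unlinked(make_cert("d0", "p2", linked = TRUE), cen)
  expect_equal(nrow(r0$allocations), 0)
  expect_length(r0$unallocated, 0)

  # two certificates matching only the same person: exactly one wins
  certs <- rbind(make_cert("d1"), make_cert("d2", dd = "1995-07-01"))
  r <- allocate_unlinked(certs, cen, seed = 3)
  expect_equal(nrow(r$allocations), 1)
  expect_equal(r$allocations$person_id, "p1")
  expect_equal(r$allocations$certificate_id, "d1")  # earlier death first
  expect_equal(r$unallocated, "d2")

  # a person with a linked death is not available
  reg2 <- rbind(make_cert("d3", "p1", linked = TRUE), make_cert("d4"))
  r2 <- allocate_unlinked(reg2, cen, seed = 3)
  expect_equal(r2$unallocated, "d4")

  # emigration before the death date excludes the person
  r3 <- allocate_unlinked(make_cert("d5"), cen, seed = 3,
                          emigrations = data.table(
                            person_id = "p1",
                            emigration_date = as.IDate("1994-01-01")))
  expect_equal(r3$unallocated, "d5")

  expect_error(allocate_unlinked(rbind(make_cert("dup"), make_cert("dup")),
                                 cen), "duplicate certificate ids")
})

test_that("tie-breaking seeds change picks but not allocation counts", {
  cen <- rbind(make_person("p1"), make_person("p2"), make_person("p3"),
               make_person("p4"))
  certs <- rbind(make_cert("d1"), make_cert("d2"))
  picks <- vapply(1:8, function(s)
    allocate_unlinked(certs, cen, seed = s)$allocations$person_id[1], "")
  counts <- vapply(1:8, function(s) {
    r <- allocate_unlinked(certs, cen, seed = s)
    c(nrow(r$allocations), sum(r$allocations$step_used == 1L))
  }, numeric(2))
  expect_gt(length(unique(picks)), 1)        # ties really are random
  expect_true(all(counts[1, ] == 2))         # but counts are invariant
  expect_true(all(counts[2, ] == 2))
  r_same1 <- allocate_unlinked(certs, cen, seed = 5)
  r_same2 <- allocate_unlinked(certs, cen, seed = 5)
  expect_identical(r_same1, r_same2)
})

test_that("allocations respect the step windows and injectivity on synthetic data", {
  run <- make_small_run(n = 8000, seed = 51)
  al <- run$alloc$allocations
  expect_gt(nrow(al), 0)
  # injectivity: no person receives two deaths, no certificate two persons
  expect_equal(anyDuplicated(al$person_id), 0)
  expect_equal(anyDuplicated(al$certificate_id), 0)
  # allocated persons never carry a linked death
  expect_length(intersect(al$person_id,
                          run$registry[linked == TRUE, person_id]), 0)
  # field-by-field window compliance
  cen <- run$census; reg <- run$registry
  m <- merge(al[, .(certificate_id, person_id, step_used)],
             reg[, .(certificate_id, sex, birth_date, canton, region,
                     nationality, marital_status)],
             by = "certificate_id")
  m <- merge(m, cen, by = "person_id", suffixes = c("_cert", "_cen"))
  dd <- abs(as.integer(m$birth_date_cert - m$birth_date_cen))
  s1 <- m$step_used == 1
  expect_true(all(m$sex_cert == m$sex_cen))
  expect_true(all(dd[s1] <= 92))
  expect_true(all(m$canton_cert[s1] == m$canton_cen[s1]))
  expect_true(all(m$nationality_cert[s1] == m$nationality_cen[s1]))
  expect_true(all(plausible_marital_transition(
    m$marital_status_cen[s1], m$marital_status_cert[s1])))
  expect_true(all(dd[!s1] <= 366))
  expect_true(all(m$region_cert[!s1] == m$region_cen[!s1]))
  expect_true(all(run$alloc$allocations$n_candidates >= 1))
})

test_that("with exact birth dates, unique step-1 candidates recover the truth", {
  run <- local({
    window <- cohort_window(as.Date("1990-12-05"), as.Date("2000-12-04"))
    pc <- population_config(8000, census_date = window$census_date,
                            age_range = c(40, 95), seed = 61)
    cen <- generate_census(pc)
    hz <- hazard_config(seed = 62)
    sim <- simulate_followup(cen, hz, window$end_date)
    uc <- unlink_config(birth_date_error = c(1, 0, 0), canton_move_prob = 0,
                        marital_change_prob = 0.3, seed = 63)
    reg <- degrade_to_registry(sim$deaths, uc)
    al <- allocate_unlinked(reg, cen, seed = 64,
                            emigrations = sim$emigrations)
    list(reg = reg, al = al)
  })
  m <- merge(run$al$allocations,
             run$reg[, .(certificate_id, truth_person_id)],
             by = "certificate_id")
  uniq1 <- m[step_used == 1 & n_candidates == 1]
  expect_gt(nrow(uniq1), 5)
  # the true person is almost always that unique candidate (an earlier
  # allocation can occasionally have consumed them)
  expect_gte(mean(uniq1$person_id == uniq1$truth_person_id), 0.95)
  # overall true-match rate is reported, not asserted
  rate <- mean(m$person_id == m$truth_person_id)
  expect_true(rate > 0 && rate <= 1)
})

test_that("agreement statistics count identical fields by stratum", {
  cen <- rbind(make_person("p1"), make_person("p2"), make_person("p3"),
               make_person("p4"))
  reg <- rbind(make_cert("d1", "p1", linked = TRUE),
               make_cert("d2", "p2", linked = TRUE),
               make_cert("d3", "p3", linked = TRUE),
               make_cert("d4", "p4", linked = TRUE, ms = "widowed"))
  res <- structure(list(allocations = data.table(
    certificate_id = character(), person_id = character(),
    step_used = integer(), n_candidates = integer()),
    unallocated = character(), seed = 1L), class = "allocation_result")
  ag <- agreement_statistics(res, cen, reg)
  main <- ag[source == "main"]
  expect_equal(main[statistic == "sex_identical_pct", value], 100)
  expect_equal(main[statistic == "birth_date_identical_pct", value], 100)
  expect_equal(main[statistic == "marital_identical_pct", value], 75)
  expect_equal(main[statistic == "marital_identical_or_plausible_pct",
                    value], 100)  # married -> widowed is plausible
  expect_equal(main[statistic == "birth_date_diff_median", value], 0)
  # empty strata are flagged, not crashed
  expect_true(all(ag[source == "step1", undefined]))
})

test_that("birth-date agreement degrades from step 1 to step 2", {
  run <- make_small_run(n = 8000, seed = 51)
  ag <- agreement_statistics(run$alloc, run$census, run$registry)
  v <- function(src, st) ag[source == src & statistic == st, value]
  expect_false(any(ag[source %in% c("main", "step1"), undefined]))
  expect_gt(v("step1", "birth_date_identical_pct"),
            v("step2", "birth_date_identical_pct"))
  expect_equal(v("step1", "sex_identical_pct"), 100)
  expect_equal(v("step2", "sex_identical_pct"), 100)
  expect_equal(v("step1", "marital_identical_or_plausible_pct"), 100)
})

test_that("allocation summary reproduces the printed percentage conventions", {
  s <- allocation_summary_counts(56413, 56265, 1053393)
  expect_equal(s$pct_unlinked_of_total, 5.4)
  expect_equal(s$pct_allocated_of_unlinked, 99.74)
  expect_equal(s$pct_unallocated_of_unlinked, 0.26)
  expect_equal(s$pct_unallocated_of_total, 0.014)
  s0 <- allocation_summary_counts(0, 0, 100)
  expect_true(s0$degenerate)
  expect_equal(s0$pct_unlinked_of_total, 0)
  expect_error(allocation_summary_counts(10, 5, 0), "positive")
  expect_error(allocation_summary_counts(10, 11, 100), "exceed")
})
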