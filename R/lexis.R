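# Person-time at risk split by calendar year, sex and attained-age group;
# death-count and rate tables; reference rates from midyear populations and
# relative-difference summaries. Exposure is measured in whole days from the
# census date to the earliest of death, emigration and the administrative end
# of follow-up, and conserved exactly under any stratification.

#' Cohort follow-up window
#'
#' @param census_date Census reference date (start of follow-up).
#' @param end_date Administrative censoring date.
#' @return List of class `cohort_window`.
#' @export
cohort_window <- function(census_date, end_date) {
  census_date <- as.IDate(census_date); end_date <- as.IDate(end_date)
  if (end_date <= census_date) stop("end_date must be after census_date")
  structure(list(census_date = census_date, end_date = end_date),
            class = "cohort_window")
}

#' Follow-up intervals from census to earliest terminal event
#'
#' One interval per person: from the census date to the earliest of the
#' person's death, emigration and the window's end date. Ties are resolved
#' death > emigration > administrative. Events dated on or before the census
#' date are an error; events after the end date are ignored (the person is
#' censored administratively).
#'
#' @param census Census table.
#' @param deaths Optional table (`person_id`, `death_date`, optionally
#'   `cause`) of deaths to treat as known.
#' @param emigrations Optional table (`person_id`, `emigration_date`).
#' @param window A [cohort_window()].
#' @return data.table `(person_id, start, stop, terminal_event, cause)`.
#' @export
follow_up_intervals <- function(census, deaths = NULL, emigrations = NULL,
                                window) {
  stopifnot(inherits(window, "cohort_window"))
  iv <- as.data.table(census)[, .(person_id)]
  iv[, `:=`(start = window$census_date, stop = window$end_date,
            terminal_event = "administrative", cause = NA_character_)]
  if (!is.null(emigrations) && nrow(emigrations)) {
    em <- as.data.table(emigrations)
    ed <- as.IDate(em$emigration_date)
    if (any(ed <= window$census_date & em$person_id %in% iv$person_id))
      stop("event date on or before the census date")
    iv[em, on = "person_id",
       `:=`(stop = pmin(stop, as.IDate(i.emigration_date)))]
    iv[em, on = "person_id",
       terminal_event := ifelse(as.IDate(i.emigration_date) <= stop,
                                "emigration", terminal_event)]
  }
  if (!is.null(deaths) && nrow(deaths)) {
    de <- as.data.table(deaths)
    if (!"cause" %in% names(de)) de[, cause := NA_character_]
    if (anyDuplicated(de$person_id))
      stop("more than one death per person")
    dd <- as.IDate(de$death_date)
    if (any(dd <= window$census_date & de$person_id %in% iv$person_id))
      stop("event date on or before the census date")
    iv[de, on = "person_id", `:=`(
      stop = pmin(stop, as.IDate(i.death_date)),
      terminal_event = ifelse(as.IDate(i.death_date) <= stop, "death",
                              terminal_event),
      cause = ifelse(as.IDate(i.death_date) <= stop, i.cause, cause))]
  }
  iv[terminal_event != "death", cause := NA_character_]
  iv[]
}

#' Person-time table by calendar year, sex and attained-age group
#'
#' Splits each follow-up interval at calendar year-ends and at the birthdays
#' where the attained-age group changes, and totals the days of exposure per
#' stratum. Conservation is exact: the summed days equal the summed interval
#' lengths.
#'
#' @param intervals From [follow_up_intervals()].
#' @param census Census table supplying `sex` and `birth_date`.
#' @param age_breaks Age-group breaks.
#' @return data.table `(year, sex, age_group, days)` of class
#'   `person_time_table` with the breaks stored in an attribute.
#' @export
person_time_table <- function(intervals, census,
                              age_breaks = default_age_breaks()) {
  iv <- as.data.table(intervals)
  if (nrow(iv)) {
    ov <- iv[, .N, by = person_id][N > 1L, person_id]
    if (length(ov)) {
      x <- iv[person_id %in% ov][order(person_id, start)]
      if (x[, any(start < shift(stop, type = "lag"), na.rm = TRUE),
            by = person_id][, any(V1)])
        stop("overlapping intervals for one person")
    }
  }
  cen <- as.data.table(census)[, .(person_id, sex, birth_date)]
  iv <- cen[iv, on = "person_id"]
  if (nrow(iv) == 0)
    return(structure(data.table(year = integer(), sex = character(),
                                age_group = character(), days = integer()),
                     class = c("person_time_table", "data.table",
                               "data.frame"),
                     age_breaks = age_breaks))
  seg <- split_intervals(iv, breaks = age_breaks)
  seg[iv, sex := i.sex, on = "person_id"]
  pt <- seg[, .(days = sum(days)), by = .(year, sex, age_group)]
  setorder(pt, year, sex, age_group)
  structure(pt, class = c("person_time_table", "data.table", "data.frame"),
            age_breaks = age_breaks)
}

count_deaths_by_stratum <- function(deaths, age_breaks) {
  de <- copy(as.data.table(deaths))
  de[, age_group := age_group_label(
    attained_age(birth_date, death_date), age_breaks)]
  de[, year := data.table::year(as.IDate(death_date))]
  de
}

#' Mortality rates per 100,000 person-years
#'
#' Joins per-stratum death counts to a person-time table and returns rates
#' per 100,000 person-years (days / 365.25), for each requested cause and
#' for all causes combined. Strata present in the person-time table but
#' without deaths get rate 0; a stratum with deaths but no person-time is an
#' error.
#'
#' @param deaths Table with `person_id`, `death_date`, `birth_date`, `sex`
#'   and a `cause` column.
#' @param person_time A [person_time_table()].
#' @param causes Cause labels to tabulate separately (default: all observed).
#' @return data.table `(year, sex, age_group, cause, deaths, person_years,
#'   rate)`, with `cause == "all"` for the all-cause rows.
#' @export
mortality_rates <- function(deaths, person_time, causes = NULL) {
  stopifnot(inherits(person_time, "person_time_table"))
  breaks <- attr(person_time, "age_breaks")
  de <- count_deaths_by_stratum(deaths, breaks)
  if (is.null(causes)) causes <- sort(unique(de$cause))
  grid <- as.data.table(person_time)
  out <- rbindlist(lapply(c("all", causes), function(cs) {
    dd <- if (cs == "all") de else de[cause == cs]
    cnt <- dd[, .(deaths = .N), by = .(year, sex, age_group)]
    orphan <- cnt[!grid, on = c("year", "sex", "age_group")]
    if (nrow(orphan))
      stop("deaths in a stratum with zero person-time (e.g. year ",
           orphan$year[1], ", ", orphan$sex[1], " ", orphan$age_group[1], ")")
    g <- cnt[grid, on = c("year", "sex", "age_group")]
    g[is.na(deaths), deaths := 0L]
    g[, `:=`(cause = cs, person_years = days / 365.25)]
    g[, rate := deaths / person_years * 1e5]
    g[, .(year, sex, age_group, cause, deaths, person_years, rate)]
  }))
  setorder(out, cause, year, sex, age_group)
  out[]
}

#' Reference rates from midyear population counts
#'
#' Death counts (all certificates, linked or not) divided by the midyear
#' population, per 100,000, by calendar year, sex, attained-age group and
#' cause (plus all causes).
#'
#' @param registry Registry table (all death certificates); cause taken from
#'   `official_cause`.
#' @param midyear data.table `(year, sex, age_group, population)`.
#' @param age_breaks Age grouping (must match the midyear table's).
#' @param causes Cause labels to tabulate separately.
#' @return data.table `(year, sex, age_group, cause, deaths, population,
#'   rate)`.
#' @export
reference_rates <- function(registry, midyear,
                            age_breaks = default_age_breaks(),
                            causes = NULL) {
  reg <- copy(as.data.table(registry))
  reg[, cause := official_cause]
  de <- count_deaths_by_stratum(reg, age_breaks)
  de <- de[year %in% unique(midyear$year)]
  if (is.null(causes)) causes <- sort(unique(de$cause))
  my <- as.data.table(midyear)
  if (any(my$population <= 0)) stop("midyear counts must be positive")
  out <- rbindlist(lapply(c("all", causes), function(cs) {
    dd <- if (cs == "all") de else de[cause == cs]
    cnt <- dd[, .(deaths = .N), by = .(year, sex, age_group)]
    miss <- cnt[!my, on = c("year", "sex", "age_group")]
    if (nrow(miss))
      stop("stratum missing from the midyear population table (year ",
           miss$year[1], ", ", miss$sex[1], " ", miss$age_group[1], ")")
    g <- cnt[my, on = c("year", "sex", "age_group")]
    g[is.na(deaths), deaths := 0L]
    g[, `:=`(cause = cs, rate = deaths / population * 1e5)]
    g[, .(year, sex, age_group, cause, deaths, population, rate)]
  }))
  setorder(out, cause, year, sex, age_group)
  out[]
}

#' Relative difference between two rate tables
#'
#' Per matched stratum the relative difference `(rate - reference_rate) /
#' reference_rate` in percent, and a mean/min/max summary over calendar years
#' within each (sex, age group, cause) series. Strata where the reference
#' rate is zero but the compared rate is not are flagged undefined and
#' excluded from summaries.
#'
#' @param snc Rate table to evaluate (e.g. cohort rates from
#'   [mortality_rates()]).
#' @param ref Reference rate table (e.g. [reference_rates()]).
#' @return List of class `rate_comparison`: `per_year` and `summary` tables.
#' @export
relative_difference <- function(snc, ref) {
  a <- as.data.table(snc)[, .(year, sex, age_group, cause, rate)]
  b <- as.data.table(ref)[, .(year, sex, age_group, cause,
                              ref_rate = rate)]
  m <- a[b, on = c("year", "sex", "age_group", "cause"), nomatch = NULL]
  m[, undefined := ref_rate == 0 & rate > 0]
  m[, rel_diff := ifelse(ref_rate == 0,
                         ifelse(rate == 0, 0, NA_real_),
                         100 * (rate - ref_rate) / ref_rate)]
  s <- m[undefined == FALSE,
         .(mean_rel_diff = mean(rel_diff), min_rel_diff = min(rel_diff),
           max_rel_diff = max(rel_diff), n_years = .N),
         by = .(sex, age_group, cause)]
  structure(list(per_year = m[], summary = s[]), class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat("Relative difference vs reference rates (%), by series:\n")
  print(x$summary, ...)
  invisible(x)
}

#' Cohort rates including or excluding unlinked deaths
#'
#' Convenience wrapper reproducing the two analysis variants: `"excluding"`
#' uses only the linked deaths (persons whose death certificate never linked
#' remain under observation until the end of the window), `"including"` adds
#' the allocated deaths, terminating the allocated person's exposure at the
#' certificate's death date.
#'
#' @param census Census table.
#' @param registry Registry table.
#' @param window A [cohort_window()].
#' @param allocations `allocations` table from [allocate_unlinked()]
#'   (required for `mode = "including"`).
#' @param emigrations Optional emigration table.
#' @param mode `"excluding"` or `"including"`.
#' @param age_breaks Age grouping.
#' @param causes Causes to tabulate.
#' @return A rate table as from [mortality_rates()].
#' @export
cohort_rates <- function(census, registry, window, allocations = NULL,
                         emigrations = NULL,
                         mode = c("excluding", "including"),
                         age_breaks = default_age_breaks(), causes = NULL) {
  mode <- match.arg(mode)
  reg <- as.data.table(registry)
  de <- reg[linked == TRUE,
            .(person_id, death_date, cause = official_cause)]
  if (mode == "including") {
    if (is.null(allocations)) stop("allocations required for mode='including'")
    al <- as.data.table(allocations)[
      reg, on = "certificate_id", nomatch = NULL,
      .(person_id = person_id, death_date = i.death_date,
        cause = i.official_cause)]
    de <- rbind(de, al)
  }
  iv <- follow_up_intervals(census, deaths = de, emigrations = emigrations,
                            window = window)
  pt <- person_time_table(iv, census, age_breaks)
  cen <- as.data.table(census)[, .(person_id, birth_date, sex)]
  dd <- cen[de, on = "person_id", nomatch = NULL]
  mortality_rates(dd, pt, causes = causes)
}
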