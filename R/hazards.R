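# Piecewise-exponential (Poisson) estimation of adjusted hazard ratios for
# education, marital status and nationality, and the comparison of estimates
# including versus excluding unlinked deaths. Follow-up is sliced by calendar
# year and attained-age group; within slices the hazard is constant, so the
# Poisson likelihood with a log-days offset is the exact likelihood of the
# piecewise-exponential model and approximates the Cox partial likelihood
# under proportional hazards.

#' Exposure specification for hazard-ratio models
#'
#' @param variable One of `"education"`, `"marital_status"`,
#'   `"nationality"`.
#' @param reference Reference level (defaults: secondary education, married,
#'   Swiss).
#' @param adjusters Adjustment covariates; by default language region,
#'   religion, urbanization, calendar year, attained-age group, sex and the
#'   other two exposure variables.
#' @param min_age Slices below this attained age are excluded (default 15
#'   for education, where the exposure is undefined for children; 0
#'   otherwise).
#' @return List of class `exposure_spec`.
#' @export
exposure_spec <- function(variable = c("education", "marital_status",
                                       "nationality"),
                          reference = NULL, adjusters = NULL,
                          min_age = NULL) {
  variable <- match.arg(variable)
  if (is.null(reference))
    reference <- switch(variable, education = "secondary",
                        marital_status = "married", nationality = "Swiss")
  others <- setdiff(c("education", "marital_status", "nationality"), variable)
  if (is.null(adjusters))
    adjusters <- c("language_region", "religion", "urbanization", "year",
                   "age_group", "sex", others)
  if (is.null(min_age)) min_age <- if (variable == "education") 15L else 0L
  structure(list(variable = variable, reference = reference,
                 adjusters = adjusters, min_age = min_age),
            class = "exposure_spec")
}

#' Expand follow-up into person-time slices
#'
#' Splits each follow-up interval at calendar year-ends and attained-age
#' group boundaries and attaches the person's covariates; the terminal slice
#' carries the event indicator and cause. Slice days sum exactly to the
#' interval lengths.
#'
#' @param intervals From [follow_up_intervals()].
#' @param covariates Census table with `person_id`, `sex`, `birth_date` and
#'   the exposure/adjuster columns.
#' @param age_breaks Age-group breaks.
#' @return data.table, one row per (person, slice): `person_id`, `year`,
#'   `age`, `age_group`, `days`, `event`, `cause`, covariates.
#' @export
expand_person_time <- function(intervals, covariates,
                               age_breaks = default_age_breaks()) {
  iv <- as.data.table(intervals)
  cov <- as.data.table(covariates)
  if (nrow(iv) == 0) {
    return(data.table(person_id = character(), year = integer(),
                      age = integer(), age_group = character(),
                      days = integer(), event = integer(),
                      cause = character()))
  }
  x <- cov[, .(person_id, birth_date)][iv, on = "person_id"]
  seg <- split_intervals(x, breaks = age_breaks)
  setorder(seg, person_id, seg_start)
  last <- seg[, .I[.N], by = person_id]$V1
  seg[, event := 0L]
  ev <- x[match(seg$person_id[last], x$person_id)]
  seg[last, event := as.integer(ev$terminal_event == "death")]
  seg[, cause := NA_character_]
  seg[last, cause := ifelse(ev$terminal_event == "death", ev$cause,
                            NA_character_)]
  out <- cov[seg, on = "person_id"]
  out[, c("seg_start", "seg_end", "row") := NULL]
  out[]
}

cause_group_labels <- function(cause, target,
                               cause_table = default_cause_table()) {
  if (target == "all") return(rep(TRUE, length(cause)))
  grp <- setNames(cause_table$group, cause_table$cause)
  if (target %in% cause_table$group) grp[cause] == target & !is.na(cause)
  else cause == target & !is.na(cause)
}

#' Fit a piecewise-exponential hazard model
#'
#' Poisson regression of slice event indicators on the exposure and
#' adjusters with offset `log(days)`, aggregated over identical covariate
#' cells for speed. Deaths from other causes censor (cause-specific
#' hazards). Returns hazard ratios with Wald 95% confidence intervals;
#' the reference level has HR exactly 1.
#'
#' @param slices From [expand_person_time()].
#' @param spec An [exposure_spec()].
#' @param cause `"all"`, a coding group (`"cancer"`, `"cardiovascular"`,
#'   `"external"`) or a cause label.
#' @param cause_table Cause-to-group map.
#' @return data.table `(level, events, person_years, hr, ci_low, ci_high,
#'   unstable)` of class `hazard_ratio_table`; the underlying glm fit is in
#'   an attribute.
#' @export
fit_hazard_model <- function(slices, spec, cause = "all",
                             cause_table = default_cause_table()) {
  stopifnot(inherits(spec, "exposure_spec"))
  sl <- copy(as.data.table(slices))
  if (spec$min_age > 0) sl <- sl[age >= spec$min_age]
  if (spec$variable == "education" && "education" %in% names(sl))
    sl <- sl[education != "not_applicable"]
  hit <- cause_group_labels(sl$cause, cause, cause_table)
  sl[, target := as.integer(event == 1L & hit)]
  vars <- intersect(c(spec$variable, spec$adjusters), names(sl))
  if (!spec$variable %in% vars) stop("exposure column missing from slices")
  agg <- sl[, .(events = sum(target), days = sum(as.numeric(days))),
            by = vars]
  if (sum(agg$events) == 0) stop("no events for cause '", cause, "'")
  if (length(unique(agg[[spec$variable]])) < 2)
    stop("exposure has a single level; no estimable contrast")
  # constant adjusters carry no information and would break the contrasts
  vars <- c(spec$variable,
            Filter(function(v) length(unique(agg[[v]])) > 1,
                   setdiff(vars, spec$variable)))
  agg[, (spec$variable) := stats::relevel(factor(get(spec$variable)),
                                          ref = spec$reference)]
  for (v in setdiff(vars, spec$variable))
    agg[, (v) := factor(get(v))]
  fml <- as.formula(paste("events ~", paste(vars, collapse = " + ")))
  fit <- glm(fml, family = poisson(), data = agg,
             offset = log(days / 365.25),
             control = glm.control(epsilon = 1e-12, maxit = 100))
  cf <- coef(fit); V <- vcov(fit)
  lv <- levels(agg[[spec$variable]])
  nm <- paste0(spec$variable, lv)
  by_level <- sl[, .(events = sum(target),
                     person_years = sum(as.numeric(days)) / 365.25),
                 by = c(spec$variable)]
  setnames(by_level, spec$variable, "level")
  out <- data.table(level = lv, hr = 1, ci_low = 1, ci_high = 1,
                    unstable = FALSE)
  for (i in seq_along(lv)[-1]) {
    b <- cf[[nm[i]]]; se <- sqrt(V[nm[i], nm[i]])
    out[i, `:=`(hr = exp(b), ci_low = exp(b - 1.96 * se),
                ci_high = exp(b + 1.96 * se))]
  }
  out <- by_level[out, on = "level"]
  out[is.na(events), `:=`(events = 0L, person_years = 0)]
  out[events == 0, unstable := TRUE]
  if (any(out$unstable))
    warning("levels with zero events produce unstable hazard ratios: ",
            paste(out$level[out$unstable], collapse = ", "))
  setcolorder(out, c("level", "events", "person_years", "hr", "ci_low",
                     "ci_high", "unstable"))
  structure(out[], class = c("hazard_ratio_table", class(out)),
            fit = fit, variable = spec$variable, cause = cause)
}

#' Hazard ratios including vs excluding unlinked deaths
#'
#' Fits the piecewise-exponential model twice: once excluding unlinked
#' deaths (their persons remain under observation until the window's end)
#' and once including the allocated deaths (terminating the allocated
#' person's exposure at the certificate's death date), and tabulates both
#' hazard-ratio columns with the absolute difference of point estimates.
#'
#' @param census Census table.
#' @param registry Registry table.
#' @param allocations `allocations` table from [allocate_unlinked()].
#' @param spec An [exposure_spec()].
#' @param cause Cause or cause group, as in [fit_hazard_model()].
#' @param window A [cohort_window()].
#' @param emigrations Optional emigration table.
#' @param age_breaks Age-group breaks.
#' @return data.table of class `hr_comparison`: per level both HR columns,
#'   CIs and `abs_diff`.
#' @export
compare_with_without <- function(census, registry, allocations, spec,
                                 cause = "all", window,
                                 emigrations = NULL,
                                 age_breaks = default_age_breaks()) {
  reg <- as.data.table(registry)
  d_excl <- reg[linked == TRUE,
                .(person_id, death_date, cause = official_cause)]
  al <- as.data.table(allocations)[
    reg, on = "certificate_id", nomatch = NULL,
    .(person_id = person_id, death_date = i.death_date,
      cause = i.official_cause)]
  d_incl <- rbind(d_excl, al)
  fit_one <- function(dd) {
    iv <- follow_up_intervals(census, deaths = dd,
                              emigrations = emigrations, window = window)
    sl <- expand_person_time(iv, census, age_breaks)
    fit_hazard_model(sl, spec, cause)
  }
  a <- fit_one(d_excl); b <- fit_one(d_incl)
  out <- merge(
    a[, .(level, events_excl = events, hr_excl = hr, lo_excl = ci_low,
          hi_excl = ci_high)],
    b[, .(level, events_incl = events, hr_incl = hr, lo_incl = ci_low,
          hi_incl = ci_high)], by = "level")
  out[, abs_diff := abs(hr_incl - hr_excl)]
  structure(out[], class = c("hr_comparison", class(out)),
            variable = spec$variable, cause = cause)
}
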