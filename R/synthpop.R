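# Synthetic census population, cause-specific mortality with a coding-regime
# switch, and degradation of a subset of certificates into "unlinked" registry
# records with retained ground truth.

sample_cat <- function(n, p) names(p)[sample.int(length(p), n, replace = TRUE,
                                                 prob = p)]

# age-group marginal -> uniform ages within the sampled group
sample_age_days <- function(n, age_marg, age_range = NULL) {
  parse_grp <- function(l) {
    if (grepl("\\+$", l)) c(as.numeric(sub("\\+", "", l)), 105)
    else as.numeric(strsplit(l, "-", fixed = TRUE)[[1]]) + c(0, 1)
  }
  b <- lapply(names(age_marg), parse_grp)
  lo <- vapply(b, `[`, 0, 1); hi <- vapply(b, `[`, 0, 2)
  p <- age_marg
  if (!is.null(age_range)) {
    lo2 <- pmax(lo, age_range[1]); hi2 <- pmin(hi, age_range[2] + 1)
    keep <- hi2 > lo2
    p <- p * ifelse(keep, (hi2 - lo2) / (hi - lo), 0)
    if (sum(p) <= 0) stop("age_range excludes all age-marginal mass")
    p <- p / sum(p); lo <- lo2; hi <- hi2
  }
  g <- sample.int(length(p), n, replace = TRUE, prob = p)
  ages <- lo[g] + runif(n) * (hi[g] - lo[g])
  round(ages * 365.25)
}

#' Generate a synthetic census wave
#'
#' Draws `n_persons` independent person records with the configured
#' categorical marginals; children under 15 are forced to marital status
#' "single" and education "not_applicable"; region and language region are
#' derived from the canton.
#'
#' @param config A [population_config()].
#' @return data.table of person records (one row per person), with columns
#'   `person_id`, `sex`, `birth_date`, `canton`, `region`, `language_region`,
#'   `nationality`, `marital_status`, `education`, `religion`,
#'   `urbanization`, `household`, `census_date`.
#' @export
generate_census <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  n <- config$n_persons
  m <- config$marginals
  cen <- data.table(
    person_id = sprintf("P%d-%07d", data.table::year(config$census_date),
                        seq_len(n)),
    sex = sample_cat(n, m$sex),
    birth_date = config$census_date - sample_age_days(n, m$age,
                                                      config$age_range),
    canton = sample_cat(n, m$canton),
    nationality = sample_cat(n, m$nationality),
    marital_status = sample_cat(n, m$marital_status),
    education = sample_cat(n, m$education),
    religion = sample_cat(n, m$religion),
    urbanization = sample_cat(n, m$urbanization),
    household = sample_cat(n, m$household),
    census_date = config$census_date
  )
  cen[, region := config$canton_to_region[canton]]
  cen[, language_region := canton_language_map()[canton]]
  age <- attained_age(cen$birth_date, config$census_date)
  cen[age < 15, `:=`(marital_status = "single", education = "not_applicable")]
  setcolorder(cen, c("person_id", "sex", "birth_date", "canton", "region",
                     "language_region", "nationality", "marital_status",
                     "education", "religion", "urbanization", "household",
                     "census_date"))
  cen[]
}

# per-person multiplicative hazard factor from the configured proportional
# covariate effects
covariate_multiplier <- function(census, covariate_log_hr) {
  lhr <- rep(0, nrow(census))
  for (v in names(covariate_log_hr)) {
    if (!v %in% names(census)) next
    eff <- covariate_log_hr[[v]]
    x <- census[[v]]
    known <- x %in% names(eff)
    lhr[known] <- lhr[known] + eff[x[known]]
  }
  exp(lhr)
}

#' Simulate mortality and emigration follow-up
#'
#' Competing exponential clocks per cause, piecewise constant over attained
#' age bands and calendar years, from the census date to `end_date`. At most
#' one terminal event (death or emigration) per person; the earliest
#' simulated event wins. Deaths receive additional cause mentions and an
#' official cause assigned by the era-appropriate coder
#' ([assign_official_cause()]), and certificate identifying fields evolved
#' from the census values (plausible marital transitions, residence moves).
#'
#' @param census A census table from [generate_census()].
#' @param hz A [hazard_config()].
#' @param end_date End of follow-up (administrative censoring date).
#' @return list with elements `deaths` (person_id, death_date,
#'   underlying_cause, mentions, official_cause, certificate fields, age at
#'   death) and `emigrations` (person_id, emigration_date).
#' @export
simulate_followup <- function(census, hz, end_date) {
  stopifnot(inherits(hz, "hazard_config"))
  end_date <- as.IDate(end_date)
  census_date <- as.IDate(census$census_date[1])
  if (end_date <= census_date) stop("end_date must be after the census date")
  set.seed(hz$seed)

  seg <- split_intervals(
    data.table(person_id = census$person_id, start = census_date,
               stop = end_date, birth_date = census$birth_date),
    breaks = hz$age_breaks)
  causes <- hz$cause_table$cause
  wide <- dcast(hz$hazard_table, sex + age_group ~ cause, value.var = "rate",
                fill = 0)
  seg[census, `:=`(sex = i.sex), on = "person_id"]
  seg <- wide[seg, on = c("sex", "age_group")]
  for (cs in causes) {
    v <- seg[[cs]]
    v[is.na(v)] <- 0
    tr <- hz$log_linear_trend[[cs]]
    if (!is.null(tr) && tr != 0)
      v <- v * exp(tr * (seg$year - hz$trend_ref_year))
    set(seg, j = cs, value = v)
  }
  setorder(seg, person_id, seg_start)
  mult <- covariate_multiplier(census, hz$covariate_log_hr)
  names(mult) <- census$person_id
  emg <- hz$emigration_hazard[seg$age_group]
  emg[is.na(emg)] <- 0
  cm <- as.matrix(seg[, ..causes]) * mult[seg$person_id]
  lamd <- (rowSums(cm) + emg) / 365.25
  seg[, haz := lamd * days]
  seg[, cum_end := cumsum(haz), by = person_id]
  seg[, cum_start := cum_end - haz]

  tgt <- rexp(nrow(census))
  names(tgt) <- census$person_id
  seg[, target := tgt[person_id]]
  ev <- which(seg$target > seg$cum_start & seg$target <= seg$cum_end &
                lamd > 0)
  events <- seg[ev]
  t_in <- (events$target - events$cum_start) / lamd[ev]
  events[, event_date := pmin(seg_start + as.integer(ceiling(t_in)), seg_end)]

  # cause draw proportional to segment-specific cause intensities
  cmat <- cbind(cm[ev, , drop = FALSE], emigration = emg[ev])
  csum <- cmat
  for (j in seq_len(ncol(csum))[-1]) csum[, j] <- csum[, j] + csum[, j - 1L]
  u <- runif(nrow(events)) * csum[, ncol(csum)]
  pick <- rowSums(u > csum) + 1L
  events[, underlying_cause := colnames(cmat)[pick]]

  emigrations <- events[underlying_cause == "emigration",
                        .(person_id, emigration_date = event_date)]
  deaths <- events[underlying_cause != "emigration",
                   .(person_id, sex, death_date = event_date, age_group,
                     underlying_cause)]
  deaths[census, `:=`(birth_date = i.birth_date), on = "person_id"]
  deaths[, age_at_death := attained_age(birth_date, death_date)]

  # additional cause mentions (sex-compatible, never the underlying cause)
  ct <- hz$cause_table
  men_mat <- matrix(FALSE, nrow(deaths), length(causes),
                    dimnames = list(NULL, causes))
  if (!is.null(hz$mention_prob) && nrow(deaths)) {
    for (cs in unique(hz$mention_prob$cause)) {
      mp <- hz$mention_prob[cause == cs]
      pr <- mp[deaths, on = c("sex", "age_group"), x.prob]
      pr[is.na(pr)] <- 0
      ss <- ct$sex_specific[match(cs, ct$cause)]
      ok <- deaths$underlying_cause != cs &
        (is.na(ss) | deaths$sex == ss)
      men_mat[, cs] <- ok & runif(nrow(deaths)) < pr
    }
  }
  men <- deaths$underlying_cause
  for (cs in causes) {
    hit <- men_mat[, cs]
    if (any(hit)) men[hit] <- paste(men[hit], cs, sep = ";")
  }
  deaths[, mentions := men]
  deaths[, official_cause := assign_official_cause(
    death_date, underlying_cause, mentions,
    regime_switch_date = hz$regime_switch_date,
    priority_causes = hz$priority_causes, cause_table = ct)]

  # certificate-field evolution between census and death
  deaths[census, `:=`(canton = i.canton, nationality = i.nationality,
                      marital_status = i.marital_status),
         on = "person_id"]
  yrs <- as.numeric(deaths$death_date - census_date) / 365.25
  p_tr <- 1 - exp(-hz$marital_transition_rate * yrs)
  do_tr <- runif(nrow(deaths)) < p_tr
  if (any(do_tr)) {
    tt <- default_marital_transitions()
    fwd <- split(tt$certificate_status[tt$census_status !=
                                         tt$certificate_status],
                 tt$census_status[tt$census_status != tt$certificate_status])
    idx <- which(do_tr)
    deaths[idx, marital_status := vapply(marital_status, function(s) {
      tg <- fwd[[s]]
      if (is.null(tg)) s else tg[sample.int(length(tg), 1)]
    }, "")]
  }
  do_mv <- runif(nrow(deaths)) < hz$residence_move_prob
  if (any(do_mv)) {
    cantons <- names(swiss_cantons())
    idx <- which(do_mv)
    deaths[idx, canton := vapply(canton, function(ct0)
      sample(setdiff(cantons, ct0), 1), "")]
  }
  rmap <- canton_region_map()
  deaths[, region := rmap[canton]]
  setcolorder(deaths, c("person_id", "sex", "birth_date", "death_date",
                        "age_at_death", "age_group", "canton", "region",
                        "nationality", "marital_status", "underlying_cause",
                        "mentions", "official_cause"))
  list(deaths = deaths[], emigrations = emigrations[])
}

#' Assign the official cause of death under the era-appropriate coder
#'
#' Before the regime switch the coder gives priority to certain cause groups
#' (by default external causes, influenza, cancer): if any mentioned cause
#' belongs to a priority group, the mentioned cause in the highest-priority
#' group becomes the official cause (the underlying cause is kept when it is
#' itself among the mentioned causes of that group). From the switch date
#' onward the coder strictly follows the underlying cause.
#'
#' @param death_date Date vector.
#' @param underlying_cause Character vector of cause labels.
#' @param mentions Character vector; per death the `";"`-separated mentioned
#'   causes (must include the underlying cause).
#' @param regime_switch_date Policy switch date (default 1995-01-01).
#' @param priority_causes Ordered character vector of priority coding groups.
#' @param cause_table Cause-to-group map, see [default_cause_table()].
#' @return Character vector of official causes.
#' @export
assign_official_cause <- function(death_date, underlying_cause, mentions,
                                  regime_switch_date = as.Date("1995-01-01"),
                                  priority_causes = default_priority_causes(),
                                  cause_table = default_cause_table()) {
  if (any(!nzchar(mentions)) || anyNA(mentions))
    stop("every death must have a non-empty mention set")
  for (u in unique(underlying_cause)) {
    i <- underlying_cause == u
    if (!all(grepl(paste0("(^|;)", u, "(;|$)"), mentions[i])))
      stop("mentions must contain the underlying cause")
  }
  grp <- setNames(cause_table$group, cause_table$cause)
  prio <- function(cs) {
    p <- match(grp[cs], priority_causes)
    ifelse(is.na(p), length(priority_causes) + 1L, p)
  }
  pre <- as.IDate(death_date) < as.IDate(regime_switch_date)
  out <- underlying_cause
  # only multi-mention pre-switch certificates can be recoded
  check <- which(pre & grepl(";", mentions, fixed = TRUE))
  ml <- strsplit(mentions[check], ";", fixed = TRUE)
  for (k in seq_along(check)) {
    i <- check[k]
    m <- ml[[k]]
    pm <- prio(m)
    best <- min(pm)
    if (best > length(priority_causes)) next       # no priority cause mentioned
    if (prio(underlying_cause[i]) == best) next    # underlying already top
    cand <- m[pm == best]
    out[i] <- cand[1]
  }
  out
}

#' Degrade death events into a registry table with unlinked records
#'
#' Each death event becomes exactly one registry record. The linkage flag is
#' drawn per stratum of (age group at death, sex, nationality, marital
#' status); unlinked records have their identifying fields perturbed per the
#' configured error model and expose no person id. The true person id is
#' retained in `truth_person_id` for evaluation only: analytic modules must
#' not read it.
#'
#' @param deaths Deaths table from [simulate_followup()].
#' @param uc An [unlink_config()].
#' @return data.table of registry records (one per death), columns
#'   `certificate_id`, certificate fields, `official_cause`, `linked`,
#'   `person_id` (NA when unlinked), `truth_person_id`.
#' @export
degrade_to_registry <- function(deaths, uc) {
  stopifnot(inherits(uc, "unlink_config"))
  set.seed(uc$seed)
  reg <- as.data.table(deaths)[, .(
    person_id, sex, birth_date, death_date, canton, region, nationality,
    marital_status, official_cause,
    age_group = age_group_label(attained_age(birth_date, death_date),
                                uc$age_breaks))]
  setorder(reg, death_date, person_id)
  reg[, certificate_id := sprintf("D%07d", .I)]
  reg[uc$unlink_prob, prob := i.prob,
      on = c("age_group", "sex", "nationality", "marital_status")]
  reg[is.na(prob), prob := 0]
  reg[, linked := runif(.N) >= prob]

  ui <- which(!reg$linked)
  if (length(ui)) {
    e <- uc$birth_date_error
    cls <- sample.int(3, length(ui), replace = TRUE, prob = e)
    err <- integer(length(ui))
    err[cls == 2] <- sample(c(-92:-1, 1:92), sum(cls == 2), replace = TRUE)
    err[cls == 3] <- sample(c(-366:-1, 1:366), sum(cls == 3), replace = TRUE)
    reg[ui, birth_date := birth_date + err]
    mv <- ui[runif(length(ui)) < uc$canton_move_prob]
    if (length(mv)) {
      cantons <- names(swiss_cantons())
      reg[mv, canton := vapply(canton, function(ct0)
        sample(setdiff(cantons, ct0), 1), "")]
      reg[mv, region := canton_region_map()[canton]]
    }
    ch <- ui[runif(length(ui)) < uc$marital_change_prob]
    if (length(ch)) {
      sts <- c("single", "married", "widowed", "divorced")
      reg[ch, marital_status := vapply(marital_status, function(s)
        sample(setdiff(sts, s), 1), "")]
    }
  }
  reg[, truth_person_id := person_id]
  reg[linked == FALSE, person_id := NA_character_]
  reg[, `:=`(prob = NULL, age_group = NULL)]
  setcolorder(reg, c("certificate_id", "sex", "birth_date", "death_date",
                     "canton", "region", "nationality", "marital_status",
                     "official_cause", "linked", "person_id",
                     "truth_person_id"))
  reg[]
}

#' Midyear population counts from generator truth
#'
#' Number of persons alive and resident (not yet dead or emigrated) on 1 July
#' of each year, by sex and attained-age group. This is the synthetic
#' analogue of the official midyear population that the reference rates
#' divide by, computed from the generator's hidden truth (all deaths,
#' including those later rendered unlinkable, end exposure here).
#'
#' @param census Census table.
#' @param deaths True deaths table from [simulate_followup()].
#' @param emigrations Emigrations table.
#' @param years Integer vector of calendar years.
#' @param age_breaks Age grouping.
#' @return data.table `(year, sex, age_group, population)`.
#' @export
midyear_population <- function(census, deaths, emigrations, years,
                               age_breaks = default_age_breaks()) {
  cen <- as.data.table(census)[, .(person_id, sex, birth_date, census_date)]
  dd <- setNames(as.integer(as.IDate(deaths$death_date)), deaths$person_id)
  ee <- setNames(as.integer(as.IDate(emigrations$emigration_date)),
                 emigrations$person_id)
  stop_i <- pmin(dd[cen$person_id], ee[cen$person_id], na.rm = TRUE)
  stop_i[is.na(stop_i)] <- .Machine$integer.max
  out <- rbindlist(lapply(years, function(y) {
    m <- as.integer(as.IDate(sprintf("%d-07-01", y)))
    alive <- as.integer(cen$census_date) < m & stop_i >= m
    if (!any(alive)) return(NULL)
    sub <- cen[alive]
    sub[, age_group := age_group_label(
      attained_age(birth_date, as.IDate(m, origin = "1970-01-01")),
      age_breaks)]
    sub[, .(year = y, population = .N), by = .(sex, age_group)]
  }))
  if (!nrow(out)) return(data.table(year = integer(), sex = character(),
                                    age_group = character(),
                                    population = integer()))
  setcolorder(out, c("year", "sex", "age_group", "population"))
  setorder(out, year, sex, age_group)
  out[]
}

#' Write the synthetic tables to CSV
#'
#' Writes `census.csv`, `deaths.csv`, `registry.csv`, `emigration.csv` and a
#' sidecar `truth.csv` (certificate id to true person id, for evaluation
#' only) with ISO-8601 dates and a header row.
#'
#' @param dir Output directory (created if needed).
#' @param census,deaths,emigrations,registry The generated tables.
#' @return Invisibly, the vector of file paths.
#' @export
write_synthetic_data <- function(dir, census, deaths, emigrations, registry) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("census.csv", "deaths.csv", "emigration.csv",
                            "registry.csv", "truth.csv"))
  fwrite(census, paths[1])
  fwrite(deaths, paths[2])
  fwrite(emigrations, paths[3])
  fwrite(registry[, !"truth_person_id"], paths[4])
  fwrite(registry[, .(certificate_id, truth_person_id)], paths[5])
  invisible(paths)
}
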