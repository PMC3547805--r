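# Configuration objects for the synthetic census / death-registry generator.
# The defaults are stylised but calibrated to the published census-2000
# marginals and to plausible Swiss cause-specific mortality levels; they are
# the fixed study conditions under which the evaluation experiments run.

#' Swiss cantons with default population weights
#'
#' The 26 canton abbreviations with approximate population shares used as the
#' default canton marginal. Shares are stylised, not official figures.
#'
#' @return Named numeric vector summing to 1.
#' @export
swiss_cantons <- function() {
  w <- c(ZH = .170, BE = .130, VD = .088, AG = .075, SG = .062, GE = .055,
         LU = .048, TI = .042, VS = .038, BL = .036, SO = .034, FR = .033,
         TG = .031, GR = .026, BS = .026, NE = .023, SZ = .018, ZG = .014,
         SH = .010, JU = .009, AR = .007, UR = .005, GL = .005, NW = .005,
         OW = .004, AI = .002)
  w / sum(w)
}

#' Canton to major-region map
#'
#' Fixed assignment of each canton to one of the seven major regions
#' (Lake Geneva, Espace Mittelland, Northwestern, Zurich, Eastern, Central,
#' Ticino).
#'
#' @return Named character vector: canton abbreviation -> region.
#' @export
canton_region_map <- function() {
  c(VD = "Lake Geneva", VS = "Lake Geneva", GE = "Lake Geneva",
    BE = "Espace Mittelland", FR = "Espace Mittelland",
    SO = "Espace Mittelland", NE = "Espace Mittelland",
    JU = "Espace Mittelland",
    BS = "Northwestern", BL = "Northwestern", AG = "Northwestern",
    ZH = "Zurich",
    GL = "Eastern", SH = "Eastern", AR = "Eastern", AI = "Eastern",
    SG = "Eastern", GR = "Eastern", TG = "Eastern",
    LU = "Central", UR = "Central", SZ = "Central", OW = "Central",
    NW = "Central", ZG = "Central",
    TI = "Ticino")
}

# Language region of the place of residence, derived from the canton.
canton_language_map <- function() {
  m <- canton_region_map()
  lang <- setNames(rep("German", length(m)), names(m))
  lang[c("VD", "GE", "VS", "FR", "NE", "JU")] <- "French"
  lang["TI"] <- "Italian"
  lang
}

#' Default categorical marginals for the census generator
#'
#' Census-2000-like marginal distributions for sex, nationality, marital
#' status (adults), education (ages 15+), religion, urbanization, household
#' type, canton, and a ten-group age distribution.
#'
#' @return Named list of named probability vectors.
#' @export
default_marginals <- function() {
  list(
    sex = c(female = .510, male = .490),
    nationality = c(Swiss = .794, `non-Swiss` = .206),
    # adult marginal; under-15s are forced to "single"
    marital_status = c(single = .2995, married = .5640, widowed = .0688,
                       divorced = .0677),
    education = c(compulsory = .366, secondary = .464, tertiary = .170),
    religion = c(protestant = .353, catholic = .418, none = .111,
                 other = .118),
    urbanization = c(urban = .285, periurban = .448, rural = .267),
    household = c(single = .154, multi = .806, institution = .040),
    canton = swiss_cantons(),
    age = c(`0-14` = .172, `15-24` = .117, `25-34` = .148, `35-44` = .164,
            `45-54` = .137, `55-64` = .109, `65-74` = .081, `75-84` = .052,
            `85-94` = .019, `95+` = .001)
  )
}

check_marginal <- function(p, name) {
  if (!is.numeric(p) || is.null(names(p)) || any(p < 0))
    stop("marginal '", name, "' must be a named non-negative numeric vector")
  if (abs(sum(p) - 1) > 1e-9)
    stop("marginal '", name, "' must sum to 1 (got ", sum(p), ")")
  invisible(p)
}

#' Population configuration
#'
#' Parameters of one census wave of the synthetic population.
#'
#' @param n_persons Number of persons (positive integer).
#' @param census_date Census reference date (default 5 December 2000; the
#'   earlier wave used 5 December 1990).
#' @param marginals Named list of categorical marginals, see
#'   [default_marginals()]. Partial lists override the defaults entry-wise.
#' @param age_range Optional length-2 numeric: restrict ages at census to
#'   `[lo, hi]` years; the default-age-marginal groups are then renormalised
#'   over that range (used for purpose-built cohorts, e.g. an elderly cohort).
#' @param canton_to_region Named map canton -> region, see
#'   [canton_region_map()].
#' @param seed Integer seed.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_persons,
                              census_date = as.Date("2000-12-05"),
                              marginals = list(),
                              age_range = NULL,
                              canton_to_region = canton_region_map(),
                              seed = 1L) {
  if (!is.numeric(n_persons) || length(n_persons) != 1 || n_persons < 1 ||
      n_persons != round(n_persons))
    stop("n_persons must be a positive integer")
  m <- utils::modifyList(default_marginals(), marginals)
  for (nm in names(m)) check_marginal(m[[nm]], nm)
  if (!all(names(m$canton) %in% names(canton_to_region)))
    stop("every canton must map to a region")
  if (length(unique(canton_to_region)) != 7)
    stop("canton_to_region must map onto exactly 7 regions")
  if (!is.null(age_range)) {
    stopifnot(length(age_range) == 2, age_range[1] >= 0,
              age_range[2] > age_range[1])
  }
  structure(list(n_persons = as.integer(n_persons),
                 census_date = as.IDate(census_date),
                 marginals = m, age_range = age_range,
                 canton_to_region = canton_to_region,
                 seed = as.integer(seed)),
            class = "population_config")
}

#' Default cause-of-death table
#'
#' Cause labels with ICD-10-style codes and their coding group. The group
#' drives the pre-1995 priority coder: causes in a priority group can
#' override a mentioned-only lower-priority underlying cause.
#'
#' @return data.table with columns `cause`, `icd10`, `group`, `sex_specific`.
#' @export
default_cause_table <- function() {
  data.table(
    cause = c("breast", "prostate", "other_cancer", "cardiovascular",
              "suicide", "other"),
    icd10 = c("C50", "C61", "C00-C97", "I00-I52", "X60-X84", "R99"),
    group = c("cancer", "cancer", "cancer", "cardiovascular", "external",
              "other"),
    sex_specific = c("female", "male", NA, NA, NA, NA)
  )
}

#' Default priority-cause ordering for the pre-1995 coder
#'
#' Coding groups in decreasing priority: external causes (accident, poisoning
#' or trauma), influenza, cancer. Before the 1995 policy change a mentioned
#' cause in one of these groups displaced a lower-priority underlying cause.
#'
#' @return Character vector of group names.
#' @export
default_priority_causes <- function() c("external", "influenza", "cancer")

# Stylised baseline hazards (deaths per person-year) by cause, sex, age band.
default_hazard_table <- function() {
  bands <- age_group_labels(default_age_breaks())
  all_cause <- c(`0-4` = .0012, `5-14` = .0002, `15-24` = .0007,
                 `25-34` = .0009, `35-44` = .0016, `45-54` = .0040,
                 `55-64` = .0090, `65-74` = .0240, `75-84` = .0650,
                 `85+` = .1600)
  suicide_share <- c(0, .02, .25, .20, .12, .08, .04, .02, .010, .004)
  cancer_share  <- c(.05, .15, .08, .12, .25, .38, .42, .40, .300, .170)
  cv_share      <- c(.05, .05, .06, .10, .15, .22, .30, .38, .430, .470)
  breast_frac   <- c(0, 0, .05, .15, .25, .25, .22, .18, .15, .12)  # of female cancer
  prostate_frac <- c(0, 0, 0, 0, .02, .05, .12, .20, .28, .32)      # of male cancer
  sex_mult <- c(female = 0.85, male = 1.20)
  out <- rbindlist(lapply(c("female", "male"), function(s) {
    ac <- all_cause * sex_mult[[s]]
    ca <- ac * cancer_share
    site <- if (s == "female") ca * breast_frac else ca * prostate_frac
    data.table(
      sex = s, age_group = bands,
      breast = if (s == "female") site else 0,
      prostate = if (s == "male") site else 0,
      other_cancer = ca - site,
      cardiovascular = ac * cv_share,
      suicide = ac * suicide_share,
      other = ac * (1 - cancer_share - cv_share - suicide_share)
    )
  }))
  melt(out, id.vars = c("sex", "age_group"), variable.name = "cause",
       value.name = "rate", variable.factor = FALSE)
}

default_trends <- function() {
  c(breast = -0.010, prostate = -0.010, other_cancer = -0.008,
    cardiovascular = -0.025, suicide = -0.010, other = -0.005)
}

default_emigration_hazard <- function() {
  bands <- age_group_labels(default_age_breaks())
  setNames(c(.002, .003, .015, .020, .012, .006, .004, .003, .002, .001),
           bands)
}

default_covariate_log_hr <- function() {
  list(
    education = c(compulsory = log(1.05), secondary = 0,
                  tertiary = log(0.90), not_applicable = 0),
    marital_status = c(single = log(1.25), married = 0, widowed = log(1.10),
                       divorced = log(1.15)),
    nationality = c(Swiss = 0, `non-Swiss` = log(0.95))
  )
}

#' Hazard and coding-regime configuration
#'
#' Event-simulation parameters: cause-specific baseline hazards (piecewise
#' constant over attained-age bands and calendar years), log-linear calendar
#' trends, additional-mention probabilities (which feed the pre-1995 priority
#' coder and hence create the coding step), proportional covariate effects,
#' emigration hazards, and the certificate-field evolution model.
#'
#' @param hazard_table data.table `(sex, age_group, cause, rate)` of baseline
#'   hazards per person-year, age groups on `age_breaks`.
#' @param age_breaks Attained-age band breaks of `hazard_table`.
#' @param cause_table See [default_cause_table()].
#' @param log_linear_trend Named per-cause slope per calendar year applied as
#'   `rate * exp(slope * (year - trend_ref_year))`.
#' @param trend_ref_year Calendar year at which baseline hazards apply.
#' @param mention_prob data.table `(cause, sex, age_group, prob)`: probability
#'   that a death whose underlying cause is *not* `cause` carries `cause` as an
#'   additional mention. `NULL` for no additional mentions.
#' @param priority_causes Ordered coding groups for the pre-1995 coder.
#' @param regime_switch_date Date the strict underlying-cause policy starts.
#' @param covariate_log_hr Named list (variable -> named log hazard ratios per
#'   level) of proportional effects on all death causes.
#' @param emigration_hazard Named per-band emigration rate per person-year.
#' @param marital_transition_rate Rate (per year) of plausible marital-status
#'   changes between census and death.
#' @param residence_move_prob Probability that the certificate canton differs
#'   from the census canton.
#' @param seed Integer seed.
#' @return An object of class `hazard_config`.
#' @export
hazard_config <- function(hazard_table = default_hazard_table(),
                          age_breaks = default_age_breaks(),
                          cause_table = default_cause_table(),
                          log_linear_trend = default_trends(),
                          trend_ref_year = 2000L,
                          mention_prob = default_mention_prob(),
                          priority_causes = default_priority_causes(),
                          regime_switch_date = as.Date("1995-01-01"),
                          covariate_log_hr = default_covariate_log_hr(),
                          emigration_hazard = default_emigration_hazard(),
                          marital_transition_rate = 0.01,
                          residence_move_prob = 0.10,
                          seed = 1L) {
  hazard_table <- as.data.table(hazard_table)
  stopifnot(all(c("sex", "age_group", "cause", "rate") %in%
                  names(hazard_table)))
  if (any(hazard_table$rate < 0)) stop("hazards must be >= 0")
  if (any(emigration_hazard < 0)) stop("hazards must be >= 0")
  if (!is.null(mention_prob)) {
    mention_prob <- as.data.table(mention_prob)
    if (any(mention_prob$prob < 0 | mention_prob$prob > 1))
      stop("mention probabilities must be in [0, 1]")
  }
  if (marital_transition_rate < 0 || residence_move_prob < 0 ||
      residence_move_prob > 1)
    stop("invalid certificate-evolution parameters")
  structure(list(
    hazard_table = hazard_table, age_breaks = age_breaks,
    cause_table = as.data.table(cause_table),
    log_linear_trend = log_linear_trend, trend_ref_year = trend_ref_year,
    mention_prob = mention_prob, priority_causes = priority_causes,
    regime_switch_date = as.IDate(regime_switch_date),
    covariate_log_hr = covariate_log_hr,
    emigration_hazard = emigration_hazard,
    marital_transition_rate = marital_transition_rate,
    residence_move_prob = residence_move_prob,
    seed = as.integer(seed)), class = "hazard_config")
}

#' Analytic coding-step factor implied by a hazard configuration
#'
#' Under the generator, the pre-1995 priority coder reassigns deaths whose
#' underlying cause is in a lower-priority group to a mentioned priority
#' cause. For a cause `c` with mention probability `m`, the official-cause
#' rate before the switch is `lambda_c + m * lambda_np` (with `lambda_np` the
#' total hazard of causes in groups of lower priority than `c`'s group),
#' and equals `lambda_c` after. The factor by which pre-switch rates must be
#' multiplied to be comparable with post-switch rates is therefore
#' `lambda_c / (lambda_c + m * lambda_np)`, computed here at the trend
#' reference year. For a cause group (e.g. all cancer) the mentioned causes'
#' probabilities are combined.
#'
#' @param hz A [hazard_config()].
#' @param cause Cause label or coding-group name (e.g. `"breast"` or
#'   `"cancer"`).
#' @param sex `"female"` or `"male"`.
#' @param age_group Age band label of `hz$age_breaks`.
#' @return The implied multiplication factor (a number in (0, 1]).
#' @export
coding_step_factor <- function(hz, cause, sex, age_group) {
  ct <- hz$cause_table
  grp <- if (cause %in% ct$group) cause else ct$group[match(cause, ct$cause)]
  if (is.na(grp)) stop("unknown cause: ", cause)
  members <- if (cause %in% ct$group) ct$cause[ct$group == cause] else cause
  prio <- match(grp, hz$priority_causes)
  if (is.na(prio)) return(1)  # non-priority causes are never inflated
  lower <- ct$cause[!(ct$group %in% hz$priority_causes[seq_len(prio)])]
  s <- sex; ag <- age_group
  rate_of <- function(cs) sum(hz$hazard_table[
    sex == s & age_group == ag & cause %in% cs, rate])
  lam_c <- rate_of(members)
  lam_np <- rate_of(lower)
  m <- 0
  if (!is.null(hz$mention_prob)) {
    mp <- hz$mention_prob[sex == s & age_group == ag & cause %in% members]
    if (nrow(mp)) m <- 1 - prod(1 - mp$prob)  # at least one member mentioned
  }
  lam_c / (lam_c + m * lam_np)
}

#' Mention probability achieving a target coding-step factor
#'
#' Inverts [coding_step_factor()]: the additional-mention probability `m` for
#' `cause` in stratum (`sex`, `age_group`) such that the implied
#' multiplication factor equals `factor`.
#'
#' @inheritParams coding_step_factor
#' @param factor Target factor in (0, 1].
#' @return Probability `m`.
#' @export
mention_prob_for_factor <- function(hz, cause, sex, age_group, factor) {
  stopifnot(factor > 0, factor <= 1)
  ct <- hz$cause_table
  grp <- ct$group[match(cause, ct$cause)]
  if (is.na(grp)) stop("unknown cause: ", cause)
  prio <- match(grp, hz$priority_causes)
  if (is.na(prio)) stop("cause '", cause, "' is not in a priority group")
  lower <- ct$cause[!(ct$group %in% hz$priority_causes[seq_len(prio)])]
  s <- sex; ag <- age_group
  rate_of <- function(cs) sum(hz$hazard_table[
    sex == s & age_group == ag & cause %in% cs, rate])
  lam_c <- rate_of(cause)
  lam_np <- rate_of(lower)
  if (lam_np == 0) stop("no lower-priority hazard to reassign from")
  lam_c * (1 - factor) / (factor * lam_np)
}

# Default mentions: breast (women) and prostate (men) mentioned on elderly
# certificates at rates chosen so the implied 85+ factors echo the published
# pattern (breast 0.80, prostate 0.84; near 1 in 75-84).
default_mention_prob <- function() {
  hz0 <- hazard_config(mention_prob = NULL)
  tgt <- rbind(
    data.table(cause = "breast", sex = "female",
               age_group = c("75-84", "85+"), factor = c(0.99, 0.80)),
    data.table(cause = "prostate", sex = "male",
               age_group = c("75-84", "85+"), factor = c(0.80, 0.84))
  )
  tgt[, prob := mapply(mention_prob_for_factor, cause = cause, sex = sex,
                       age_group = age_group, factor = factor,
                       MoreArgs = list(hz = hz0))]
  tgt[, .(cause, sex, age_group, prob)]
}

#' Unlinkage configuration
#'
#' Probability that a death certificate fails the main census-mortality
#' linkage, by stratum of (age group at death, sex, nationality, marital
#' status), plus the perturbation model describing how unlinked certificates
#' deviate from the truth (the assumed data-error mechanism behind linkage
#' failure).
#'
#' @param unlink_prob data.table `(age_group, sex, nationality,
#'   marital_status, prob)`; see [default_unlink_table()]. A constant may be
#'   given instead.
#' @param age_breaks Age grouping of `unlink_prob`.
#' @param birth_date_error Length-3 probabilities of (exact, within +/-92
#'   days, within +/-366 days) birth-date error for unlinked certificates.
#' @param canton_move_prob Probability the unlinked certificate's canton is
#'   replaced by a random other canton.
#' @param marital_change_prob Probability the unlinked certificate's marital
#'   status is replaced by a random other status.
#' @param seed Integer seed.
#' @return An object of class `unlink_config`.
#' @export
unlink_config <- function(unlink_prob = default_unlink_table(),
                          age_breaks = default_age_breaks(),
                          birth_date_error = c(exact = .5, q = .4, y = .1),
                          canton_move_prob = 0.5,
                          marital_change_prob = 0.15,
                          seed = 1L) {
  if (is.numeric(unlink_prob) && length(unlink_prob) == 1) {
    p <- unlink_prob
    unlink_prob <- default_unlink_table()
    unlink_prob[, prob := p]
  }
  unlink_prob <- as.data.table(unlink_prob)
  stopifnot(all(c("age_group", "sex", "nationality", "marital_status",
                  "prob") %in% names(unlink_prob)))
  if (any(unlink_prob$prob < 0 | unlink_prob$prob > 1))
    stop("unlink probabilities must be in [0, 1]")
  if (abs(sum(birth_date_error) - 1) > 1e-9 || any(birth_date_error < 0))
    stop("birth_date_error must be a probability vector summing to 1")
  if (canton_move_prob < 0 || canton_move_prob > 1 ||
      marital_change_prob < 0 || marital_change_prob > 1)
    stop("perturbation probabilities must be in [0, 1]")
  structure(list(unlink_prob = unlink_prob, age_breaks = age_breaks,
                 birth_date_error = birth_date_error,
                 canton_move_prob = canton_move_prob,
                 marital_change_prob = marital_change_prob,
                 seed = as.integer(seed)), class = "unlink_config")
}

#' Default stratified unlinkage probabilities
#'
#' Built multiplicatively from an age-band base (high in children and young
#' adults, ~4% in the elderly) and modifiers for sex, nationality (non-Swiss
#' markedly higher) and marital status (singles higher), echoing the
#' published pattern of unlinked-death characteristics; the overall unlinked
#' share of deaths lands near 5%.
#'
#' @param age_breaks Age-band breaks.
#' @return data.table `(age_group, sex, nationality, marital_status, prob)`.
#' @export
default_unlink_table <- function(age_breaks = default_age_breaks()) {
  bands <- age_group_labels(age_breaks)
  base <- setNames(c(.14, .14, .22, .19, .11, .072, .047, .032, .032, .032),
                   bands)
  g <- CJ(age_group = bands, sex = c("female", "male"),
          nationality = c("Swiss", "non-Swiss"),
          marital_status = c("single", "married", "widowed", "divorced"))
  sex_m <- c(female = 0.92, male = 1.08)
  nat_m <- c(Swiss = 0.88, `non-Swiss` = 2.30)
  mar_m <- c(single = 1.40, married = 1.00, widowed = 0.82, divorced = 1.05)
  g[, prob := pmin(base[age_group] * sex_m[sex] * nat_m[nationality] *
                     mar_m[marital_status], 0.95)]
  g[]
}
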