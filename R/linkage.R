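# Two-step pragmatic allocation of unlinked death certificates to census
# records. Step 1 matches on sex, canton, nationality, birth date within 3
# months and a plausible marital-status change; step 2 relaxes to sex, major
# region and birth date within one year. Impossible sex-specific causes are
# excluded, ties are broken uniformly at random with a recorded seed, and a
# person can absorb at most one death.

#' Plausible marital-status transition table
#'
#' Identity pairs plus the legally possible changes between census and death:
#' single to married, married to widowed or divorced, divorced to married,
#' widowed to married. A reversal to never-married (e.g. widowed to single)
#' is impossible.
#'
#' @return data.table with columns `census_status`, `certificate_status`.
#' @export
default_marital_transitions <- function() {
  sts <- c("single", "married", "widowed", "divorced")
  rbind(
    data.table(census_status = sts, certificate_status = sts),
    data.table(
      census_status = c("single", "married", "married", "divorced",
                        "widowed"),
      certificate_status = c("married", "widowed", "divorced", "married",
                             "married"))
  )
}

#' Is a marital-status change plausible?
#'
#' @param census_status,certificate_status Status labels (vectors recycled).
#' @param table Allowed-pair table, see [default_marital_transitions()].
#' @return Logical vector.
#' @export
plausible_marital_transition <- function(census_status, certificate_status,
                                         table = default_marital_transitions()) {
  sts <- c("single", "married", "widowed", "divorced")
  if (!all(census_status %in% sts) || !all(certificate_status %in% sts))
    stop("unknown marital status label")
  paste(census_status, certificate_status) %in%
    paste(table$census_status, table$certificate_status)
}

#' Sex / cause-of-death compatibility rule
#'
#' Prevents impossible matches for gender-specific causes: under the default
#' cause table a female record cannot carry prostate cancer (C61) and a male
#' record cannot carry breast cancer (C50).
#'
#' @param sex Sex labels.
#' @param official_cause Cause labels.
#' @param cause_table See [default_cause_table()].
#' @return Logical vector, `FALSE` where the pair is impossible.
#' @export
sex_cause_compatible <- function(sex, official_cause,
                                 cause_table = default_cause_table()) {
  ct <- cause_table
  key <- match(official_cause, ct$cause)
  if (anyNA(key)) {
    # accept ICD-style codes as well as labels
    key2 <- match(official_cause, ct$icd10)
    key[is.na(key)] <- key2[is.na(key)]
  }
  if (anyNA(key)) stop("unknown cause label: ",
                       paste(unique(official_cause[is.na(key)]),
                             collapse = ", "))
  req <- ct$sex_specific[key]
  is.na(req) | req == sex
}

#' Matching criteria of one allocation step
#'
#' @param step 1 or 2.
#' @return List with the step's required-equal fields, birth-date tolerance in
#'   days (92 for step 1, 366 for step 2) and geography level.
#' @export
match_criteria <- function(step) {
  if (step == 1) {
    list(step = 1L,
         fields_required_equal = c("sex", "canton", "nationality"),
         birth_date_tolerance = 92L, geography_level = "canton",
         marital_plausibility = TRUE)
  } else if (step == 2) {
    list(step = 2L, fields_required_equal = c("sex", "region"),
         birth_date_tolerance = 366L, geography_level = "region",
         marital_plausibility = FALSE)
  } else stop("step must be 1 or 2")
}

#' Census candidates for one certificate
#'
#' Returns the person ids satisfying the step's matching criteria for the
#' given certificate among the supplied census records (which the caller
#' restricts to unconsumed, eligible persons). Step 1 requires equal sex,
#' canton and nationality, birth date within 92 days and a plausible marital
#' transition; step 2 requires equal sex and region and birth date within 366
#' days. Persons whose sex is incompatible with the certificate's cause are
#' excluded at both steps.
#'
#' @param cert One registry record (list or one-row data.frame).
#' @param census Census table of eligible persons.
#' @param criteria A [match_criteria()].
#' @param transitions Marital-transition table.
#' @param cause_table Cause table for the impossible-match rule.
#' @return Character vector of person ids (possibly empty).
#' @export
find_candidates <- function(cert, census, criteria,
                            transitions = default_marital_transitions(),
                            cause_table = default_cause_table()) {
  cen <- as.data.table(census)
  keep <- cen$sex == cert$sex &
    abs(as.integer(as.IDate(cen$birth_date) - as.IDate(cert$birth_date))) <=
      criteria$birth_date_tolerance
  if (criteria$geography_level == "canton") {
    keep <- keep & cen$canton == cert$canton &
      cen$nationality == cert$nationality
  } else {
    keep <- keep & cen$region == cert$region
  }
  if (isTRUE(criteria$marital_plausibility)) {
    keep <- keep & plausible_marital_transition(
      cen$marital_status, cert$marital_status, transitions)
  }
  keep <- keep & sex_cause_compatible(cen$sex, cert$official_cause,
                                      cause_table)
  cen$person_id[keep]
}

#' Allocate unlinked death certificates to census records
#'
#' Certificates are processed in a fixed deterministic order (death date,
#' then certificate id). For each unlinked certificate the step-1 candidate
#' set is computed among still-available persons; if non-empty one candidate
#' is chosen uniformly at random, otherwise step 2 is tried; if both fail the
#' certificate remains unallocated. Persons already carrying a linked death,
#' consumed by an earlier allocation, or emigrated before the certificate's
#' death date are not eligible.
#'
#' @param registry Registry table (linked and unlinked records).
#' @param census Census table.
#' @param transitions Marital-transition table.
#' @param seed Integer seed for the tie-breaking draws.
#' @param emigrations Optional emigration table (`person_id`,
#'   `emigration_date`).
#' @param cause_table Cause table for the impossible-match rule.
#' @return An object of class `allocation_result`: list with `allocations`
#'   (certificate_id, person_id, step_used, n_candidates), `unallocated`
#'   (certificate ids), and `seed`.
#' @export
allocate_unlinked <- function(registry, census,
                              transitions = default_marital_transitions(),
                              seed = 1L, emigrations = NULL,
                              cause_table = default_cause_table()) {
  reg <- as.data.table(registry)
  if (anyDuplicated(reg$certificate_id))
    stop("duplicate certificate ids")
  cen <- as.data.table(census)[, .(
    person_id, sex, birth_date = as.IDate(birth_date), canton, region,
    nationality, marital_status)]
  cen[, bd := as.integer(birth_date)]
  cen[, row := .I]

  available <- rep(TRUE, nrow(cen))
  linked_pid <- reg[linked == TRUE, person_id]
  available[cen$person_id %in% linked_pid] <- FALSE
  emig <- rep(NA_integer_, nrow(cen))
  if (!is.null(emigrations) && nrow(emigrations)) {
    m <- match(cen$person_id, emigrations$person_id)
    emig <- as.integer(as.IDate(emigrations$emigration_date))[m]
  }

  # allowed-transition lookup matrix census x certificate status
  sts <- c("single", "married", "widowed", "divorced")
  allowed <- matrix(FALSE, 4, 4, dimnames = list(sts, sts))
  allowed[cbind(transitions$census_status, transitions$certificate_status)] <-
    TRUE

  # sex-specific cause exclusions: candidate sets share the certificate's sex
  sex_ok <- function(s, cause) sex_cause_compatible(s, cause, cause_table)

  k1 <- copy(cen); setkey(k1, sex, canton, nationality)
  k2 <- copy(cen); setkey(k2, sex, region)

  un <- reg[linked == FALSE]
  setorder(un, death_date, certificate_id)
  n_un <- nrow(un)
  alloc_pid <- character(n_un); alloc_step <- integer(n_un)
  alloc_nc <- integer(n_un)
  un_bd <- as.integer(as.IDate(un$birth_date))
  un_dd <- as.integer(as.IDate(un$death_date))

  set.seed(seed)
  for (i in seq_len(n_un)) {
    if (!sex_ok(un$sex[i], un$official_cause[i])) next
    cand <- NULL; step <- 0L
    s1 <- k1[.(un$sex[i], un$canton[i], un$nationality[i]), nomatch = NULL]
    if (nrow(s1)) {
      ok <- available[s1$row] & abs(s1$bd - un_bd[i]) <= 92L &
        allowed[cbind(s1$marital_status, un$marital_status[i])] &
        (is.na(emig[s1$row]) | emig[s1$row] >= un_dd[i])
      if (any(ok)) { cand <- s1$row[ok]; step <- 1L }
    }
    if (is.null(cand)) {
      s2 <- k2[.(un$sex[i], un$region[i]), nomatch = NULL]
      if (nrow(s2)) {
        ok <- available[s2$row] & abs(s2$bd - un_bd[i]) <= 366L &
          (is.na(emig[s2$row]) | emig[s2$row] >= un_dd[i])
        if (any(ok)) { cand <- s2$row[ok]; step <- 2L }
      }
    }
    if (is.null(cand)) next
    chosen <- cand[sample.int(length(cand), 1L)]
    available[chosen] <- FALSE
    alloc_pid[i] <- cen$person_id[chosen]
    alloc_step[i] <- step
    alloc_nc[i] <- length(cand)
  }

  hit <- alloc_step > 0L
  structure(list(
    allocations = data.table(
      certificate_id = un$certificate_id[hit],
      person_id = alloc_pid[hit],
      step_used = alloc_step[hit],
      n_candidates = alloc_nc[hit]),
    unallocated = un$certificate_id[!hit],
    seed = as.integer(seed)), class = "allocation_result")
}

#' @export
print.allocation_result <- function(x, ...) {
  n <- nrow(x$allocations) + length(x$unallocated)
  cat("Two-step allocation of", n, "unlinked certificates\n")
  if (n > 0) {
    cat(sprintf("  allocated: %d (step 1: %d, step 2: %d); unallocated: %d\n",
                nrow(x$allocations), sum(x$allocations$step_used == 1L),
                sum(x$allocations$step_used == 2L), length(x$unallocated)))
  }
  cat("  tie-break seed:", x$seed, "\n")
  invisible(x)
}

#' Agreement between census and certificate fields
#'
#' For the main linkage (linked records vs their census person) and for each
#' allocation step, the percentage of pairs with identical sex, birth date,
#' marital status (also identical-or-plausible), nationality and place of
#' residence (canton), plus quartiles of the signed birth-date difference in
#' days (certificate minus census).
#'
#' @param result An [allocate_unlinked()] result.
#' @param census Census table.
#' @param registry Registry table.
#' @param transitions Marital-transition table.
#' @return data.table with one row per (source, statistic); `value` is NA
#'   with `undefined = TRUE` for empty strata.
#' @export
agreement_statistics <- function(result, census, registry,
                                 transitions = default_marital_transitions()) {
  reg <- as.data.table(registry)
  cen <- as.data.table(census)
  pairs <- rbind(
    reg[linked == TRUE, .(certificate_id, person_id, source = "main")],
    if (nrow(result$allocations))
      result$allocations[, .(certificate_id, person_id,
                             source = paste0("step", step_used))]
  )
  stats_for <- function(p) {
    if (is.null(p) || nrow(p) == 0) {
      return(data.table(
        statistic = c("sex_identical_pct", "birth_date_identical_pct",
                      "birth_date_diff_q25", "birth_date_diff_median",
                      "birth_date_diff_q75", "marital_identical_pct",
                      "marital_identical_or_plausible_pct",
                      "nationality_identical_pct", "residence_identical_pct"),
        value = NA_real_, undefined = TRUE))
    }
    cert <- reg[, .(certificate_id, c_sex = sex,
                    c_birth_date = as.IDate(birth_date),
                    c_marital = marital_status, c_nationality = nationality,
                    c_canton = canton)][p, on = "certificate_id"]
    d <- cen[, .(person_id, sex, birth_date = as.IDate(birth_date),
                 marital_status, nationality, canton)][
      cert, on = "person_id"]
    dd <- as.integer(d$c_birth_date - d$birth_date)
    q <- stats::quantile(dd, c(.25, .5, .75), type = 2)
    data.table(
      statistic = c("sex_identical_pct", "birth_date_identical_pct",
                    "birth_date_diff_q25", "birth_date_diff_median",
                    "birth_date_diff_q75", "marital_identical_pct",
                    "marital_identical_or_plausible_pct",
                    "nationality_identical_pct", "residence_identical_pct"),
      value = c(100 * mean(d$c_sex == d$sex),
                100 * mean(dd == 0), q[[1]], q[[2]], q[[3]],
                100 * mean(d$c_marital == d$marital_status),
                100 * mean(plausible_marital_transition(
                  d$marital_status, d$c_marital, transitions)),
                100 * mean(d$c_nationality == d$nationality),
                100 * mean(d$c_canton == d$canton)),
      undefined = FALSE)
  }
  out <- rbindlist(lapply(c("main", "step1", "step2"), function(s)
    cbind(source = s, stats_for(pairs[source == s]))))
  out[]
}

#' Allocation summary percentages
#'
#' Counts and percentages in the printed convention of linkage reports:
#' percentages at or above 1% to one decimal place, below 1% to two
#' significant figures; the allocated share of unlinked deaths is printed as
#' 100 minus its rounded complement so that the pair is consistent (e.g.
#' 99.74 / 0.26).
#'
#' @param n_unlinked Number of unlinked certificates.
#' @param n_allocated Number successfully allocated.
#' @param total_deaths Total deaths recorded in the period.
#' @return List of counts and percentages; `degenerate = TRUE` (with NA
#'   percentages for the unlinked-denominator quantities) when
#'   `n_unlinked = 0`.
#' @export
allocation_summary_counts <- function(n_unlinked, n_allocated, total_deaths) {
  if (total_deaths <= 0) stop("total_deaths must be positive")
  if (n_allocated > n_unlinked) stop("n_allocated cannot exceed n_unlinked")
  if (n_unlinked > total_deaths)
    stop("total_deaths must be at least the number of unlinked certificates")
  n_unallocated <- n_unlinked - n_allocated
  if (n_unlinked == 0) {
    return(list(n_unlinked = 0L, n_allocated = 0L, n_unallocated = 0L,
                total_deaths = total_deaths,
                pct_unlinked_of_total = 0,
                pct_allocated_of_unlinked = NA_real_,
                pct_unallocated_of_unlinked = NA_real_,
                pct_unallocated_of_total = 0, degenerate = TRUE))
  }
  pct_unalloc <- format_pct(100 * n_unallocated / n_unlinked)
  list(
    n_unlinked = n_unlinked, n_allocated = n_allocated,
    n_unallocated = n_unallocated, total_deaths = total_deaths,
    pct_unlinked_of_total = format_pct(100 * n_unlinked / total_deaths),
    pct_allocated_of_unlinked = 100 - pct_unalloc,
    pct_unallocated_of_unlinked = pct_unalloc,
    pct_unallocated_of_total = format_pct(100 * n_unallocated / total_deaths),
    degenerate = FALSE)
}

#' @rdname allocation_summary_counts
#' @param result An [allocate_unlinked()] result.
#' @param total_deaths Total number of deaths (linked and unlinked).
#' @export
allocation_summary <- function(result, total_deaths) {
  stopifnot(inherits(result, "allocation_result"))
  n_un <- nrow(result$allocations) + length(result$unallocated)
  allocation_summary_counts(n_un, nrow(result$allocations), total_deaths)
}
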