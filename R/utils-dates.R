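# Calendar utilities shared by the Lexis splitter, the event simulator and the
# linkage rules. Exposure is counted in whole days, each day labelled by its
# end date: the day ending on date d belongs to calendar year year(d) and to
# the attained age the person holds on d. This makes person-time conservation
# exact in integer days under any stratification.

#' Attained age in completed years
#'
#' Age a person born on `birth` has attained on date `d` (age increments on
#' the birthday; a 29 February birthday increments on 1 March in common
#' years).
#'
#' @param birth,d `Date` vectors (recycled).
#' @return Integer vector of completed years.
#' @export
attained_age <- function(birth, d) {
  birth <- as.IDate(birth); d <- as.IDate(d)
  yb <- data.table::year(birth); yd <- data.table::year(d)
  before <- (data.table::month(d) < data.table::month(birth)) |
    (data.table::month(d) == data.table::month(birth) &
       data.table::mday(d) < data.table::mday(birth))
  as.integer(yd - yb - before)
}

# Date of the k-th birthday; 29 Feb maps to 1 Mar in common years (consistent
# with attained_age()). Integer arithmetic: only distinct years are parsed.
birthday_date <- function(birth, k) {
  birth <- as.IDate(birth)
  y <- data.table::year(birth) + as.integer(k)
  m <- data.table::month(birth)
  d <- data.table::mday(birth)
  uy <- sort(unique(y))
  jan1 <- as.integer(as.IDate(paste0(uy, "-01-01")))
  j <- jan1[match(y, uy)]
  cum <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L, 273L, 304L, 334L)
  leap <- y %% 4L == 0L & (y %% 100L != 0L | y %% 400L == 0L)
  off <- cum[m] + (d - 1L) + as.integer(leap & m > 2L)
  as.IDate(j + off, origin = "1970-01-01")
}

#' Default attained-age groups
#'
#' Ten-year groups up to 84 with a final open 85+ group (a finer 0-4 / 5-14
#' split at childhood), matching the convention of national mortality tables.
#'
#' @return Numeric vector of left endpoints, ending in `Inf`.
#' @export
default_age_breaks <- function() c(0, 5, 15, 25, 35, 45, 55, 65, 75, 85, Inf)

#' Label ages by age group
#'
#' @param age Numeric vector of ages in completed years.
#' @param breaks Left endpoints of the groups, last element `Inf`.
#' @return Character vector of labels such as `"75-84"`, `"85+"`.
#' @export
age_group_label <- function(age, breaks = default_age_breaks()) {
  stopifnot(is.numeric(breaks), length(breaks) >= 2, !is.unsorted(breaks),
            is.infinite(breaks[length(breaks)]))
  labs <- age_group_labels(breaks)
  labs[findInterval(age, breaks)]
}

age_group_labels <- function(breaks) {
  k <- length(breaks) - 1L
  lo <- breaks[seq_len(k)]
  hi <- breaks[seq_len(k) + 1L] - 1
  ifelse(is.infinite(breaks[seq_len(k) + 1L]),
         paste0(lo, "+"), paste0(lo, "-", hi))
}

# Split exposure intervals (start, stop] at calendar year-ends and at
# birthdays where the attained-age group changes. `dt` needs columns
# person_id, start, stop, birth_date (and is not modified). Returns one row
# per (person, segment) with seg_start, seg_end, year, age, age_group, days.
# Fully vectorised; no per-person loop.
split_intervals <- function(dt, breaks = default_age_breaks()) {
  x <- data.table(
    person_id = dt$person_id,
    start = as.IDate(dt$start), stop = as.IDate(dt$stop),
    birth = as.IDate(dt$birth_date)
  )
  if (any(x$stop <= x$start)) stop("intervals must satisfy start < stop")
  n <- nrow(x)
  if (n == 0L) {
    return(data.table(person_id = x$person_id, seg_start = x$start,
                      seg_end = x$stop, year = integer(), age = integer(),
                      age_group = character(), days = integer()))
  }
  x[, row := .I]

  # year-end cuts strictly inside (start, stop)
  y0 <- data.table::year(x$start); y1 <- data.table::year(x$stop)
  nyr <- pmax(y1 - y0, 0L)
  idx <- rep.int(x$row, nyr)
  # sequence(nyr) yields 1..nyr[i] per row, aligned with rep.int(row, nyr)
  yrs <- y0[idx] + sequence(nyr)
  uy <- sort(unique(yrs))
  lut <- as.IDate(paste0(uy - 1L, "-12-31"))  # parse each distinct year once
  cuts_y <- data.table(row = idx, cut = lut[match(yrs, uy)])

  # age-group-boundary birthdays (minus one day) strictly inside (start, stop)
  finite_breaks <- breaks[is.finite(breaks) & breaks > 0]
  a0 <- attained_age(x$birth, x$start)
  a1 <- attained_age(x$birth, x$stop)
  cr <- lapply(finite_breaks, function(b) {
    hit <- which(a0 < b & a1 >= b)
    if (!length(hit)) return(NULL)
    data.table(row = x$row[hit],
               cut = birthday_date(x$birth[hit], b) - 1L)
  })
  cuts_a <- rbindlist(cr)

  cuts <- rbind(cuts_y, cuts_a,
                data.table(row = x$row, cut = x$stop))
  cuts <- cuts[cut > x$start[row] & cut <= x$stop[row]]
  cuts <- unique(cuts)
  setorder(cuts, row, cut)
  cuts[, seg_start := shift(cut, type = "lag"), by = row]
  cuts[is.na(seg_start), seg_start := x$start[row]]

  seg <- data.table(
    person_id = x$person_id[cuts$row],
    row = cuts$row,
    seg_start = cuts$seg_start,
    seg_end = cuts$cut
  )
  seg[, days := as.integer(seg_end - seg_start)]
  seg[, year := data.table::year(seg_end)]
  seg[, age := attained_age(x$birth[row], seg_end)]
  seg[, age_group := age_group_label(age, breaks)]
  seg[]
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Percentage printing convention of the summary tables: one decimal at or
# above 1%, two significant figures below 1%.
format_pct <- function(x) ifelse(x >= 1, round(x, 1), signif(x, 2))
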