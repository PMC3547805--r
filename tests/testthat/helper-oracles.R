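suppressMessages(library(data.table))

# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the likelihood maximiser is hand-written (multi-start
# quasi-Newton on the Poisson log-likelihood, not IRLS), and the person-time
# oracle enumerates exposure day by day with base R date handling.

# Poisson negative log-likelihood (up to a constant) and analytic gradient.
poisson_nll <- function(beta, X, y, off) {
  eta <- drop(X %*% beta) + off
  sum(exp(eta)) - sum(y * eta)
}
poisson_nll_grad <- function(beta, X, y, off) {
  eta <- drop(X %*% beta) + off
  drop(crossprod(X, exp(eta) - y))
}

# Brute-force maximum likelihood: a coarse grid of starting points around a
# crude intercept estimate, each refined by BFGS with the analytic gradient
# and polished by Nelder-Mead.
brute_force_poisson <- function(X, y, off) {
  p <- ncol(X)
  s0 <- c(log(sum(y) / sum(exp(off))), rep(0, p - 1))
  starts <- list(s0)
  for (j in seq_len(p)) {
    for (d in c(-1, 1)) {
      s <- s0; s[j] <- s[j] + d
      starts <- c(starts, list(s))
    }
  }
  best <- NULL
  for (s in starts) {
    o <- tryCatch(stats::optim(s, poisson_nll, poisson_nll_grad, X = X,
                               y = y, off = off, method = "BFGS",
                               control = list(maxit = 10000,
                                              reltol = 1e-15)),
                  error = function(e) NULL)
    if (is.null(o)) next
    o2 <- stats::optim(o$par, poisson_nll, X = X, y = y, off = off,
                       method = "Nelder-Mead",
                       control = list(maxit = 50000, reltol = 1e-15))
    o3 <- stats::optim(o2$par, poisson_nll, poisson_nll_grad, X = X, y = y,
                       off = off, method = "BFGS",
                       control = list(maxit = 10000, reltol = 1e-15))
    if (is.null(best) || o3$value < best$value) best <- o3
  }
  best$par
}

# Day-by-day person-time enumeration: each exposure day is labelled by its
# end date; attained age computed with base R formatting.
oracle_person_time <- function(person_id, start, stop, birth, sex, breaks) {
  rows <- list()
  for (i in seq_along(person_id)) {
    d <- seq(as.Date(start[i]) + 1, as.Date(stop[i]), by = "day")
    yr <- as.integer(format(d, "%Y"))
    md <- format(d, "%m%d")
    bmd <- format(as.Date(birth[i]), "%m%d")
    age <- yr - as.integer(format(as.Date(birth[i]), "%Y")) - (md < bmd)
    lab <- cohortbridge::age_group_label(age, breaks)
    tab <- table(paste(yr, sex[i], lab, sep = "|"))
    rows[[i]] <- data.frame(key = names(tab), days = as.integer(tab))
  }
  agg <- stats::aggregate(days ~ key, data = do.call(rbind, rows), FUN = sum)
  parts <- do.call(rbind, strsplit(agg$key, "|", fixed = TRUE))
  data.frame(year = as.integer(parts[, 1]), sex = parts[, 2],
             age_group = parts[, 3], days = agg$days,
             stringsAsFactors = FALSE)
}

# Small shared synthetic run for structural tests (generated once per file
# load; fixed seeds make it deterministic).
make_small_run <- function(n = 8000, seed = 11L) {
  window <- cohort_window(as.Date("1990-12-05"), as.Date("2000-12-04"))
  pc <- population_config(n, census_date = window$census_date,
                          age_range = c(40, 95), seed = seed)
  cen <- generate_census(pc)
  hz <- hazard_config(seed = seed + 1L)
  sim <- simulate_followup(cen, hz, window$end_date)
  uc <- unlink_config(seed = seed + 2L)
  reg <- degrade_to_registry(sim$deaths, uc)
  alloc <- allocate_unlinked(reg, cen, seed = seed + 3L,
                             emigrations = sim$emigrations)
  list(window = window, census = cen, deaths = sim$deaths,
       emigrations = sim$emigrations, registry = reg, alloc = alloc)
}
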