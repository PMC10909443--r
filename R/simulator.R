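#' The twelve translocation simulation scenarios
#'
#' Each scenario crosses an initial (translocated) population size `N1` of
#' 15 or 30, a total superpopulation `N` of 500 or 2000, and a capture
#' probability regime (low 0.1--0.3, mid 0.4--0.6, high 0.7--0.9). All
#' scenarios use 10 survey occasions at 6-month spacing, monthly survival
#' drawn uniformly in 0.94--0.99 per interval, entry proportions drawn in
#' 0.1--0.2 for the free occasions, no new entrants at occasions 2--3, and
#' 250 replicates.
#'
#' @return data frame with one row per scenario.
#' @export
scenario_table <- function() {
  p_lo <- c(0.1, 0.4, 0.7)
  p_hi <- c(0.3, 0.6, 0.9)
  grid <- expand.grid(p = 1:3, N1 = c(15L, 30L), N = c(500L, 2000L))
  data.frame(scenario = 1:12, N1 = grid$N1, N = grid$N,
             p_low = p_lo[grid$p], p_high = p_hi[grid$p],
             beta_low = 0.1, beta_high = 0.2,
             phi_low = 0.94, phi_high = 0.99,
             n_occasions = 10L, interval_months = 6L, replicates = 250L)
}

#' Build a simulation scenario specification
#'
#' @param id scenario number 1--12 (row of [scenario_table()]).
#' @param replicates number of replicates to run (default 250).
#' @param phi_scale how to read the drawn survival values: `"monthly"`
#'   (default; interval survival = value^6), `"interval"` (drawn value used
#'   as the 6-month survival directly) or `"annual"` (value^(1/2) per
#'   6-month interval).
#' @return object of class `tjs_scenario`.
#' @export
tjs_scenario <- function(id, replicates = NULL,
                         phi_scale = c("monthly", "interval", "annual")) {
  tab <- scenario_table()
  if (!id %in% tab$scenario) stop("scenario id must be in 1..12")
  row <- tab[tab$scenario == id, ]
  structure(list(
    scenario = as.integer(id), N1 = row$N1, N = row$N,
    p_range = c(row$p_low, row$p_high),
    beta_range = c(row$beta_low, row$beta_high),
    phi_range = c(row$phi_low, row$phi_high),
    T = row$n_occasions, interval_months = row$interval_months,
    zero_entry = c(2L, 3L), tau = 4L,
    replicates = as.integer(replicates %||% row$replicates),
    phi_scale = match.arg(phi_scale)), class = "tjs_scenario")
}

scenario_design <- function(spec) {
  tjs_design(spec$T,
             occasion_times = spec$interval_months * (0:(spec$T - 1)),
             tau = spec$tau)
}

#' Draw the true per-occasion parameters for one scenario replicate
#'
#' Capture probability at the release is 1; `p_2..p_T` are uniform in the
#' scenario's range. Monthly survival is drawn uniformly per interval.
#' The release entry proportion is `beta_1 = N1 / N`; entries at the
#' zero-entry occasions are 0; the remaining entries are uniform draws
#' rescaled so the whole vector sums to 1 (i.e. the free entries sum to
#' `1 - N1/N`, leaving the translocated share intact).
#'
#' @param spec a [tjs_scenario()].
#' @param seed optional RNG seed.
#' @return truth list with monthly and interval-scale survival, `p`,
#'   `beta` and the scenario.
#' @export
draw_scenario_parameters <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T <- spec$T
  p <- c(1, stats::runif(T - 1, spec$p_range[1], spec$p_range[2]))
  draw <- stats::runif(T - 1, spec$phi_range[1], spec$phi_range[2])
  phi_monthly <- switch(spec$phi_scale,
                        monthly = draw,
                        interval = draw ^ (1 / spec$interval_months),
                        annual = draw ^ (1 / 12))
  phi_interval <- phi_monthly ^ spec$interval_months
  beta <- numeric(T)
  beta[1] <- spec$N1 / spec$N
  free <- setdiff(seq_len(T), c(1L, spec$zero_entry))
  raw <- stats::runif(length(free), spec$beta_range[1], spec$beta_range[2])
  beta[free] <- raw / sum(raw) * (1 - beta[1])
  list(spec = spec, p = p, phi_monthly = phi_monthly,
       phi = phi_interval, beta = beta)
}

#' Simulate presence (alive) histories for one replicate
#'
#' Each of the `N` superpopulation members is assigned an entry occasion by
#' a multinomial draw over `beta`, then survives each subsequent interval
#' with the interval survival probability; death removes it for the rest of
#' the study. The realised abundance `N_t` counts individuals alive at
#' occasion `t`.
#'
#' @param truth output of [draw_scenario_parameters()].
#' @param seed optional RNG seed.
#' @return list with `entry` and `last_alive` occasion per individual and
#'   the true abundance vector `N_t`.
#' @export
simulate_presence <- function(truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- truth$spec
  T <- spec$T
  entry <- sample.int(T, spec$N, replace = TRUE, prob = truth$beta)
  last_alive <- entry
  for (t in seq_len(T - 1)) {
    at_risk <- last_alive == t & entry <= t
    n <- sum(at_risk)
    if (n)
      last_alive[at_risk] <- last_alive[at_risk] +
        stats::rbinom(n, 1, truth$phi[t]) * 1L
  }
  # last_alive now holds, per individual, the last occasion it was alive
  Nt <- vapply(seq_len(T), function(t)
    sum(entry <= t & last_alive >= t), integer(1))
  list(entry = entry, last_alive = last_alive, Nt = Nt)
}

#' Simulate capture histories from presence histories
#'
#' Detection is Bernoulli with the occasion's capture probability for every
#' occasion an individual is alive; occasion-1 entrants are the
#' translocated cohort and are detected at the release with probability 1.
#' Individuals never detected are dropped from the observed set (they enter
#' the likelihood only via the never-seen probability).
#'
#' @param fates output of [simulate_presence()].
#' @param truth output of [draw_scenario_parameters()].
#' @param seed optional RNG seed.
#' @return `list(design, histories, truth, fates)` where `design` carries
#'   `D` and `n0` as realised.
#' @export
simulate_captures <- function(fates, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- truth$spec
  T <- spec$T
  N <- spec$N
  det <- matrix(0L, N, T)
  for (t in seq_len(T)) {
    alive <- fates$entry <= t & fates$last_alive >= t
    n <- sum(alive)
    if (n) det[alive, t] <- stats::rbinom(n, 1, truth$p[t])
  }
  det[fates$entry == 1L, 1] <- 1L  # release detection is certain
  seen <- rowSums(det) > 0
  origin <- ifelse(fates$entry == 1L, "translocated", "wild")
  histories <- tjs_histories(det[seen, , drop = FALSE], origin[seen],
                             id = sprintf("sim%05d", which(seen)))
  design <- derive_design_counts(scenario_design(spec), histories)
  list(design = design, histories = histories, truth = truth,
       fates = fates)
}

#' Simulate one full scenario replicate
#'
#' Draws the truth parameters, the presence histories and the capture
#' histories with a single seed, so the same seed reproduces the dataset
#' byte for byte.
#'
#' @param spec a [tjs_scenario()].
#' @param seed RNG seed for the replicate.
#' @return as [simulate_captures()], plus the true abundance in
#'   `$fates$Nt`.
#' @export
simulate_scenario <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- draw_scenario_parameters(spec)
  fates <- simulate_presence(truth)
  simulate_captures(fates, truth)
}

#' Write a truth sidecar file for a simulated dataset
#'
#' Plain tab-separated table of the per-occasion truth: `beta`, `p`, the
#' interval and monthly survival entering each interval, and the realised
#' abundance `N_t`.
#'
#' @param sim output of [simulate_scenario()].
#' @param path output file.
#' @export
write_truth <- function(sim, path) {
  T <- sim$truth$spec$T
  df <- data.frame(occasion = seq_len(T), beta = sim$truth$beta,
                   p = sim$truth$p,
                   phi_monthly = c(sim$truth$phi_monthly, NA),
                   phi_interval = c(sim$truth$phi, NA),
                   Nt = sim$fates$Nt)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
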