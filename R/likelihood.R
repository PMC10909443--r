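#' Natural-scale parameter set for a POPAN-style model
#'
#' Bundles the superpopulation size `N` (wild-born individuals only in the
#' translocation model; everyone in the standard model), per-interval
#' apparent survival probabilities `phi` (already on the interval scale,
#' i.e. monthly survival raised to the interval length where intervals are
#' uneven), per-occasion capture probabilities `p`, and entry proportions
#' `beta` indexed by entry occasion.
#'
#' `beta` is stored as a length-`T` vector. In the translocation model the
#' entries before `tau` are identically zero and the rest sum to 1; in the
#' standard model all `T` entries are free and sum to 1.
#'
#' @param N nonnegative superpopulation size (need not be integer).
#' @param phi survival probabilities, length `T - 1`, in `(0, 1]`.
#' @param p capture probabilities, length `T`, in `[0, 1]`.
#' @param beta entry proportions, length `T`, summing to 1.
#' @return object of class `tjs_params`.
#' @export
tjs_params <- function(N, phi, p, beta) {
  if (N < 0) stop("N must be nonnegative")
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(beta < 0 | beta > 1)) stop("beta must lie in [0, 1]")
  if (abs(sum(beta) - 1) > 1e-10)
    stop("beta must sum to 1 (within 1e-10)")
  if (length(p) != length(phi) + 1L || length(beta) != length(p))
    stop("lengths must satisfy length(phi) = T - 1, length(p) = length(beta) = T")
  structure(list(N = as.numeric(N), phi = as.numeric(phi),
                 p = as.numeric(p), beta = as.numeric(beta)),
            class = "tjs_params")
}

check_params_design <- function(params, design) {
  if (length(params$p) != design$T)
    stop("parameter vectors do not match design T")
  invisible(NULL)
}

hist_prob <- function(log_value) {
  structure(list(value = exp(log_value), log_value = log_value),
            class = "tjs_prob")
}

param_logs <- function(params) {
  list(lbeta = log(params$beta), lphi = log(params$phi),
       l1mphi = log1p(-params$phi), lp = log(params$p),
       l1mp = log1p(-params$p))
}

#' History probabilities under the translocation Jolly--Seber model
#'
#' `prob_history_wild()` evaluates the probability of a wild-born
#' individual's capture history: a sum over its latent entry occasion
#' `b` (from `tau` to its first capture) and last-alive occasion `d` (from
#' its last capture to `T`) of the entry, survival, death and detection
#' terms. `prob_history_translocated()` is the analogue for a translocated
#' individual, whose entry is known to be occasion 1 and whose release
#' detection has probability 1, so no entry-proportion factor appears.
#' `prob_never_seen()` is the probability that a wild superpopulation
#' member is never detected; it exponentiates over the `N - (D - n0)`
#' unseen individuals in the joint likelihood.
#'
#' @param x binary detection vector of length `T` (for the history-level
#'   functions).
#' @param params a [tjs_params()].
#' @param design a [tjs_design()].
#' @return list with elements `value` and `log_value`.
#' @export
prob_history_wild <- function(x, params, design) {
  x <- as.integer(x)
  f <- which(x == 1)[1]
  if (is.na(f)) stop("history has no detections")
  if (f < design$tau)
    stop("wild history detected before tau: contract violation")
  lg <- param_logs(params)
  lp <- cpp_log_prob_histories(matrix(x, 1), f, max(which(x == 1)), FALSE,
                               design$tau, lg$lbeta, lg$lphi, lg$l1mphi,
                               lg$lp, lg$l1mp)
  hist_prob(lp[1])
}

#' @rdname prob_history_wild
#' @export
prob_history_translocated <- function(x, params, design) {
  x <- as.integer(x)
  if (x[1] != 1L)
    stop("translocated history must be detected at release: contract violation")
  params$p[1] <- 1  # release detection is certain
  lg <- param_logs(params)
  lp <- cpp_log_prob_histories(matrix(x, 1), 1L, max(which(x == 1)), TRUE,
                               design$tau, lg$lbeta, lg$lphi, lg$l1mphi,
                               lg$lp, lg$l1mp)
  hist_prob(lp[1])
}

#' @rdname prob_history_wild
#' @param tau_override entry window start; defaults to the design's `tau`
#'   (set to 1 for the standard model's never-seen probability).
#' @export
prob_never_seen <- function(params, design, tau_override = NULL) {
  tau <- if (is.null(tau_override)) design$tau else as.integer(tau_override)
  lg <- param_logs(params)
  hist_prob(cpp_log_prob_never(design$T, tau, lg$lbeta, lg$lphi,
                               lg$l1mphi, lg$l1mp))
}

# Collapse histories to unique (detections, origin) rows with weights; the
# per-fit cost is dominated by likelihood evaluations, which then scale
# with the number of distinct histories rather than D.
pack_histories <- function(histories, T) {
  m <- detection_matrix(histories)
  tr <- histories$origin == "translocated"
  key <- paste(ifelse(tr, "t", "w"), apply(m, 1, paste, collapse = ""))
  u <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[u])))
  mu <- m[u, , drop = FALSE]
  list(X = mu, w = w, transloc = tr[u],
       f = apply(mu, 1, function(r) which(r == 1)[1]),
       dl = apply(mu, 1, function(r) max(which(r == 1))))
}

loglik_packed <- function(params, packed, design, model) {
  T <- design$T
  tau <- if (model == "translocation") design$tau else 1L
  if (model == "translocation") params$p[1] <- 1
  else packed$transloc[] <- FALSE  # unconstrained POPAN ignores origin
  Dw <- if (model == "translocation") design$D - design$n0 else design$D
  if (params$N < Dw - 1e-9)
    stop("N must be at least the number of observed (wild) individuals")
  lg <- param_logs(params)
  lph <- cpp_log_prob_histories(packed$X, packed$f, packed$dl,
                                packed$transloc, tau, lg$lbeta, lg$lphi,
                                lg$l1mphi, lg$lp, lg$l1mp)
  ll <- sum(packed$w * lph) +
    lgamma(params$N + 1) - lgamma(params$N - Dw + 1)
  nunseen <- params$N - Dw
  if (nunseen > 0) {
    lp0 <- cpp_log_prob_never(T, tau, lg$lbeta, lg$lphi, lg$l1mphi, lg$l1mp)
    ll <- ll + nunseen * lp0
  }
  # log(0) guard: optimizers recover from a large finite penalty
  if (!is.finite(ll)) ll <- -1e300
  ll
}

#' Joint log-likelihood of the translocation Jolly--Seber model
#'
#' The joint likelihood multiplies (i) the conditional probabilities of the
#' `n0` translocated histories (entry known, release detection certain),
#' (ii) the wild-history probabilities, (iii) a binomial-coefficient term
#' `N! / (N - (D - n0))!` in log-gamma form (so `N` may be non-integer
#' during optimisation) and (iv) the never-seen probability raised to the
#' number of unseen wild individuals `N - (D - n0)`.
#'
#' @param params a [tjs_params()]; `N` is the wild-born superpopulation.
#' @param design a [tjs_design()].
#' @param histories capture-history data frame.
#' @return log-likelihood (up to the constant multinomial ordering factor).
#' @export
loglik_translocation <- function(params, design, histories) {
  validate_data(design, histories)
  check_params_design(params, design)
  loglik_packed(params, pack_histories(histories, design$T), design,
                "translocation")
}

#' Log-likelihood of the standard (unconstrained) POPAN model
#'
#' All individuals are treated identically: origin is ignored, entry is
#' allowed from occasion 1, `p_1` is a free parameter and the
#' superpopulation `N` includes the translocated individuals, so the
#' unseen-history exponent is `N - D`.
#'
#' @inheritParams loglik_translocation
#' @export
loglik_standard_popan <- function(params, design, histories) {
  validate_data(design, histories)
  check_params_design(params, design)
  loglik_packed(params, pack_histories(histories, design$T), design,
                "standard")
}

#' Group-structured joint log-likelihood
#'
#' The likelihood with group effects is the product over groups of the
#' single-group likelihood evaluated on that group's histories with that
#' group's parameters; the total superpopulation is the sum of the
#' per-group `N_g`.
#'
#' @param params_per_group named list of [tjs_params()], one per group
#'   label.
#' @param design a [tjs_design()].
#' @param histories capture-history data frame with a `group` column.
#' @param model `"translocation"` or `"standard"`.
#' @return total log-likelihood.
#' @export
loglik_groups <- function(params_per_group, design, histories,
                          model = c("translocation", "standard")) {
  model <- match.arg(model)
  fun <- if (model == "translocation") loglik_translocation
         else loglik_standard_popan
  grp <- histories$group
  grp[is.na(grp)] <- ""
  labs <- unique(grp)
  if (!all(labs %in% names(params_per_group)))
    stop("unknown group label: ",
         paste(setdiff(labs, names(params_per_group)), collapse = ", "))
  total <- 0
  for (g in labs) {
    sub <- histories[grp == g, , drop = FALSE]
    dsub <- derive_design_counts(design, sub)
    total <- total + fun(params_per_group[[g]], dsub, sub)
  }
  total
}
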