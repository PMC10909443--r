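#' Model specification for a POPAN-style fit
#'
#' Each parameter family gets a one-sided formula built from `1` (constant),
#' `time` (fully time dependent), `group` (separate level per group label)
#' and names of per-occasion covariate columns in the design. Links are the
#' standard ones: log for `N`, logit for `phi` (on the monthly scale) and
#' `p`, and a multinomial logit over the free entry occasions for `beta`
#' (reference category: the last free entry occasion).
#'
#' Fixed constraints are honoured exactly in the parameter expansion and
#' excluded from the parameter count `k`: the translocation model always
#' fixes `p_1 = 1` (the release) and `beta = 0` before `tau`; further
#' per-occasion values of `p` can be pinned through `p_fixed`.
#'
#' The covariate name `moon` is treated as a lunar phase in `[0, 1)` and
#' expanded to a sine/cosine pair by default, so detection can peak between
#' the new and full moon; set `moon_encoding = "linear"` to use the raw
#' phase instead.
#'
#' @param N,phi,p,beta one-sided formulas (`beta` supports `~time` only).
#' @param p_fixed optional named numeric vector, names = occasion indices,
#'   values = fixed capture probabilities.
#' @param moon_encoding `"harmonic"` or `"linear"`.
#' @param name optional label used in AIC tables.
#' @return object of class `tjs_model_spec`.
#' @export
tjs_model_spec <- function(N = ~1, phi = ~1, p = ~1, beta = ~time,
                           p_fixed = NULL, moon_encoding = "harmonic",
                           name = NULL) {
  terms_of <- function(f) {
    if (identical(deparse(f[[length(f)]]), "1")) character(0)
    else all.vars(f)
  }
  fmt <- function(tms) if (length(tms)) paste(tms, collapse = "+") else "1"
  tN <- terms_of(N); tphi <- terms_of(phi); tp <- terms_of(p)
  tb <- terms_of(beta)
  structure(list(N = tN, phi = tphi, p = tp, beta = tb, p_fixed = p_fixed,
                 moon_encoding = match.arg(moon_encoding,
                                           c("harmonic", "linear")),
                 name = name %||% sprintf("N~%s phi~%s p~%s", fmt(tN),
                                          fmt(tphi), fmt(tp))),
            class = "tjs_model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a model spec from a plain-text config
#'
#' Lines of the form `phi: ~time`, `p: ~effort + airtemp + moon`,
#' `N: ~group`; omitted families default to constant (`beta` to `~time`).
#' @param path config file.
#' @return a [tjs_model_spec()].
#' @export
read_model_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"),
                        character(1)))
  getf <- function(k, default) {
    i <- match(k, keys)
    if (is.na(i)) default else stats::as.formula(vals[i])
  }
  tjs_model_spec(N = getf("N", ~1), phi = getf("phi", ~1),
                 p = getf("p", ~1), beta = getf("beta", ~time))
}

# Design matrix for one parameter family over (occasion) rows.
family_matrix <- function(terms, occasions, design, spec, family) {
  n <- length(occasions)
  cols <- list(`(Intercept)` = rep(1, n))
  for (tm in terms) {
    if (tm == "time") {
      if (n > 1)
        for (j in occasions[-1])
          cols[[paste0("t", j)]] <- as.numeric(occasions == j)
    } else if (tm == "group") {
      # handled at the group level (separate intercepts appended later)
    } else {
      cv <- design$covariates
      if (is.null(cv) || !tm %in% names(cv))
        stop(sprintf("covariate '%s' not found in design", tm))
      v <- cv[[tm]][occasions]
      if (tm == "moon" && spec$moon_encoding == "harmonic") {
        cols[[paste0(tm, "_sin")]] <- sin(2 * pi * v)
        cols[[paste0(tm, "_cos")]] <- cos(2 * pi * v)
      } else {
        cols[[tm]] <- v
      }
    }
  }
  do.call(cbind, cols)
}

# Parameter layout: maps the flat coefficient vector theta to the natural
# parameters of each group. Group terms give each group its own column
# block for that family; families without a group term share coefficients.
build_layout <- function(spec, design, model) {
  T <- design$T
  use_groups <- length(design$groups) > 0 &&
    (("group" %in% spec$N) || ("group" %in% spec$phi) ||
     ("group" %in% spec$p))
  groups <- if (use_groups) design$groups else ""
  G <- length(groups)
  if (use_groups && !("group" %in% spec$N))
    stop("group-structured fits require N ~ group")

  fixed_p <- integer(0)
  if (model == "translocation") fixed_p <- 1L
  if (!is.null(spec$p_fixed))
    fixed_p <- sort(unique(c(fixed_p, as.integer(names(spec$p_fixed)))))
  free_p <- setdiff(seq_len(T), fixed_p)
  free_beta <- if (model == "translocation") design$tau:T else seq_len(T)

  XN <- matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)"))
  Xphi <- family_matrix(spec$phi, seq_len(T - 1), design, spec, "phi")
  Xp <- family_matrix(spec$p, free_p, design, spec, "p")

  kN <- if ("group" %in% spec$N) G else 1L
  kphi_g <- ncol(Xphi); kp_g <- ncol(Xp)
  kphi <- if ("group" %in% spec$phi) G * kphi_g else kphi_g
  kp <- if ("group" %in% spec$p) G * kp_g else kp_g
  kbeta <- length(free_beta) - 1L

  k <- kN + kphi + kp + kbeta
  idx <- list(N = seq_len(kN),
              phi = kN + seq_len(kphi),
              p = kN + kphi + seq_len(kp),
              beta = kN + kphi + kp + seq_len(kbeta))
  list(groups = groups, G = G, use_groups = use_groups,
       Xphi = Xphi, Xp = Xp, free_p = free_p, fixed_p = fixed_p,
       free_beta = free_beta, kN = kN, kphi_g = kphi_g, kp_g = kp_g,
       kbeta = kbeta, k = k, idx = idx, model = model)
}

softmax_ref_last <- function(th) {
  e <- exp(c(th, 0) - max(c(th, 0)))
  e / sum(e)
}

expand_one_group <- function(theta, layout, spec, design, g,
                             support_offset) {
  T <- design$T
  thN <- theta[layout$idx$N]
  etaN <- if ("group" %in% spec$N) thN[g] else thN[1]
  N <- support_offset[g] + exp(etaN)

  thphi <- theta[layout$idx$phi]
  if ("group" %in% spec$phi)
    thphi <- thphi[(g - 1) * layout$kphi_g + seq_len(layout$kphi_g)]
  phi_monthly <- stats::plogis(drop(layout$Xphi %*% thphi))
  phi <- phi_monthly ^ design$intervals

  thp <- theta[layout$idx$p]
  if ("group" %in% spec$p)
    thp <- thp[(g - 1) * layout$kp_g + seq_len(layout$kp_g)]
  p <- rep(NA_real_, T)
  p[layout$free_p] <- stats::plogis(drop(layout$Xp %*% thp))
  if (layout$model == "translocation") p[1] <- 1
  if (!is.null(spec$p_fixed))
    p[as.integer(names(spec$p_fixed))] <- spec$p_fixed

  beta <- numeric(T)
  beta[layout$free_beta] <- softmax_ref_last(theta[layout$idx$beta])

  pr <- tjs_params(N, phi, p, beta)
  attr(pr, "phi_monthly") <- phi_monthly
  pr
}

#' Expand link-scale coefficients to natural parameters
#'
#' Applies the log link for `N` (shifted by `support_offset` so the fitted
#' `N` cannot drop below the observed count during optimisation), the logit
#' link for monthly `phi` and for `p`, and the multinomial logit (reference
#' = last free entry occasion) for `beta`. Fixed values (`p_1 = 1`,
#' pre-`tau` `beta = 0` in the translocation model) bypass the links.
#'
#' @param theta coefficient vector of length `k`.
#' @param spec a [tjs_model_spec()].
#' @param design a [tjs_design()].
#' @param model `"translocation"` or `"standard"`.
#' @param support_offset additive offset for `N` per group (default 0, the
#'   plain log link).
#' @return named list of [tjs_params()], one per group (a single unnamed
#'   group when no group structure is used).
#' @export
expand_parameters <- function(theta, spec, design,
                              model = c("translocation", "standard"),
                              support_offset = NULL) {
  model <- match.arg(model)
  layout <- build_layout(spec, design, model)
  if (length(theta) != layout$k)
    stop(sprintf("theta has length %d but the spec needs k = %d",
                 length(theta), layout$k))
  if (is.null(support_offset)) support_offset <- rep(0, layout$G)
  out <- lapply(seq_len(layout$G), function(g)
    expand_one_group(theta, layout, spec, design, g, support_offset))
  names(out) <- layout$groups
  out
}

split_by_group <- function(histories, layout) {
  if (!layout$use_groups) return(list(histories))
  grp <- histories$group
  lapply(layout$groups, function(g) histories[grp %in% g, , drop = FALSE])
}

default_init <- function(layout, design, packs, model) {
  theta <- numeric(layout$k)
  theta[layout$idx$N] <- log(10 + sum(vapply(packs, function(pk)
    sum(pk$w), numeric(1))) / layout$G)
  theta[layout$idx$phi][seq(1, length(layout$idx$phi),
                            by = layout$kphi_g)] <- stats::qlogis(0.97)
  cap <- do.call(rbind, lapply(packs, function(pk) pk$X * pk$w))
  D <- sum(vapply(packs, function(pk) sum(pk$w), numeric(1)))
  rate <- sum(cap[, -1]) / (D * (design$T - 1))
  rate <- min(max(rate, 0.05), 0.9)
  theta[layout$idx$p][seq(1, length(layout$idx$p),
                          by = layout$kp_g)] <- stats::qlogis(rate)
  theta
}

#' Maximum-likelihood fit of a translocation or standard POPAN model
#'
#' Optimises the log-likelihood on the unconstrained link scale with
#' `stats::nlminb` (quasi-Newton), restarting from `nstarts` perturbed
#' initial coefficient vectors and returning the best local optimum. `N` is
#' parameterised as `(observed count) + exp(theta_N)` so the support
#' constraint holds smoothly throughout optimisation.
#'
#' @param histories capture-history data frame.
#' @param design a [tjs_design()].
#' @param spec a [tjs_model_spec()].
#' @param model `"translocation"` (known `n0` released at occasion 1,
#'   `p_1 = 1`, no entries before `tau`) or `"standard"` (unconstrained
#'   POPAN: origin ignored, entry free from occasion 1).
#' @param options list: `nstarts` (default 5), `seed` (default 1), `init`
#'   (starting coefficients), `control` passed to `nlminb`.
#' @return object of class `tjs_fit` with coefficients, natural parameters
#'   per group, log-likelihood, `k`, AIC, the derived abundance trajectory,
#'   convergence diagnostics and boundary flags.
#' @export
fit_mle <- function(histories, design, spec = tjs_model_spec(),
                    model = c("translocation", "standard"),
                    options = list()) {
  model <- match.arg(model)
  design <- derive_design_counts(design, histories)
  validate_data(design, histories)
  opts <- utils::modifyList(list(nstarts = 5L, seed = 1L, init = NULL,
                                 control = list(iter.max = 500,
                                                eval.max = 2000)),
                            options)
  layout <- build_layout(spec, design, model)
  subsets <- split_by_group(histories, layout)
  designs <- lapply(subsets, function(s) derive_design_counts(design, s))
  packs <- lapply(subsets, function(s) pack_histories(s, design$T))
  offsets <- vapply(designs, function(d)
    if (model == "translocation") d$D - d$n0 else d$D, numeric(1))

  negll <- function(theta) {
    val <- tryCatch({
      ll <- 0
      for (g in seq_len(layout$G)) {
        pr <- expand_one_group(theta, layout, spec, design, g, offsets)
        ll <- ll + loglik_packed(pr, packs[[g]], designs[[g]], model)
      }
      -ll
    }, error = function(e) 1e300)
    if (!is.finite(val)) 1e300 else val
  }

  init <- opts$init %||% default_init(layout, design, packs, model)
  best <- NULL; objs <- numeric(0)
  for (s in seq_len(opts$nstarts)) {
    th0 <- init
    if (s > 1) {
      set.seed(opts$seed * 1000L + s)
      th0 <- init + stats::rnorm(layout$k, 0, 0.5)
    }
    res <- tryCatch(stats::nlminb(th0, negll, control = opts$control),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    objs <- c(objs, res$objective)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best) || best$objective >= 1e299) {
    return(structure(list(converged = FALSE, model = model, spec = spec,
                          message = "all optimisation starts failed"),
                     class = "tjs_fit"))
  }
  theta <- best$par
  params <- expand_parameters(theta, spec, design, model, offsets)
  logLik <- -best$objective
  k <- layout$k
  boundary <- character(0)
  for (g in seq_len(layout$G)) {
    pm <- attr(params[[g]], "phi_monthly")
    lab <- if (layout$use_groups) paste0(" [", layout$groups[g], "]") else ""
    if (any(pm > 1 - 1e-4)) boundary <- c(boundary, paste0("phi at upper boundary", lab))
    if (any(pm < 1e-4)) boundary <- c(boundary, paste0("phi at lower boundary", lab))
    pf <- params[[g]]$p[layout$free_p]
    if (any(pf > 1 - 1e-4)) boundary <- c(boundary, paste0("p at upper boundary", lab))
    if (any(pf < 1e-4)) boundary <- c(boundary, paste0("p at lower boundary", lab))
    if (params[[g]]$N - offsets[g] < 1e-3)
      boundary <- c(boundary, paste0("N at lower support boundary", lab))
  }
  fit <- structure(list(
    theta = theta, params = params, logLik = logLik, k = k,
    AIC = 2 * k - 2 * logLik, model = model, spec = spec,
    design = design, layout = layout, offsets = offsets,
    group_designs = designs, converged = best$convergence == 0,
    nstarts_used = length(objs), start_objectives = objs,
    boundary = boundary), class = "tjs_fit")
  ab <- derive_abundance(fit, design)
  fit$abundance <- ab$total
  fit$abundance_by_group <- ab$by_group
  fit
}

#' @export
print.tjs_fit <- function(x, ...) {
  cat(sprintf("%s Jolly-Seber fit (%s)\n", x$model,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (!is.null(x$logLik))
    cat(sprintf("  logLik = %.3f, k = %d, AIC = %.2f\n",
                x$logLik, x$k, x$AIC))
  if (!is.null(x$params)) {
    Ns <- vapply(x$params, function(p) p$N, numeric(1))
    cat(sprintf("  N-hat = %.1f%s\n", sum(Ns),
                if (length(Ns) > 1)
                  paste0(" (", paste(sprintf("%s: %.1f", names(Ns), Ns),
                                     collapse = ", "), ")") else ""))
  }
  if (length(x$boundary))
    cat("  boundary estimates:", paste(x$boundary, collapse = "; "), "\n")
  invisible(x)
}

# Low-level recursion: N_1 is the release count (translocation) or the
# occasion-1 entrants N * beta_1 (standard); thereafter
# N_{t+1} = N_t * phi_t + N * beta_{t+1}, with phi_t the interval survival.
abundance_recursion <- function(params, design, n0, model) {
  T <- design$T
  Nt <- numeric(T)
  Nt[1] <- if (model == "translocation") n0 else params$N * params$beta[1]
  for (t in seq_len(T - 1))
    Nt[t + 1] <- Nt[t] * params$phi[t] + params$N * params$beta[t + 1]
  Nt
}

#' Derived abundance trajectory
#'
#' Abundance per occasion follows the recursion
#' `N_{t+1} = N_t * phi_t + N * beta_{t+1}` seeded with `N_1 = n0` for the
#' translocation model (the release count is known) and `N_1 = N * beta_1`
#' for the standard model. With group structure, group trajectories are
#' computed separately (each seeded with its own release count) and summed.
#'
#' @param fit a `tjs_fit`.
#' @param design a [tjs_design()]; defaults to the fit's design.
#' @return list with `total` (length-`T` vector) and `by_group` (matrix,
#'   occasions x groups).
#' @export
derive_abundance <- function(fit, design = fit$design) {
  by_group <- vapply(seq_along(fit$params), function(g) {
    dg <- fit$group_designs[[g]]
    abundance_recursion(fit$params[[g]], design, dg$n0, fit$model)
  }, numeric(design$T))
  by_group <- matrix(by_group, nrow = design$T,
                     dimnames = list(NULL, names(fit$params)))
  list(total = rowSums(by_group), by_group = by_group)
}

#' Nonparametric bootstrap confidence intervals
#'
#' Resamples individuals with replacement, stratified by origin (each
#' resample contains exactly `n0` translocated and `D - n0` wild
#' individuals), refits the model, and returns percentile intervals for the
#' natural parameters and the derived abundance trajectory.
#'
#' @inheritParams fit_mle
#' @param B number of bootstrap replicates (default 999).
#' @param seed RNG seed; the same seed reproduces identical intervals.
#' @param level confidence level (default 0.95).
#' @return list with `level`, `B_used`, `failures`, the base `fit`, matrix
#'   `abundance` (occasions x c(lower, upper)) and interval tables for `N`,
#'   `phi`, `p`, `beta`.
#' @export
bootstrap_ci <- function(histories, design, spec = tjs_model_spec(),
                         model = c("translocation", "standard"),
                         B = 999L, seed = 1L, level = 0.95,
                         options = list()) {
  model <- match.arg(model)
  if (B < 2) stop("B must be at least 2")
  design <- derive_design_counts(design, histories)
  base <- fit_mle(histories, design, spec, model, options)
  if (!isTRUE(base$converged)) stop("base fit did not converge")
  tr_idx <- which(histories$origin == "translocated")
  wd_idx <- which(histories$origin == "wild")
  refit_opts <- utils::modifyList(options,
                                  list(nstarts = 1L, init = base$theta))
  draws_ab <- matrix(NA_real_, B, design$T)
  draws_N <- numeric(B)
  draws_phi <- matrix(NA_real_, B, design$T - 1)
  draws_p <- matrix(NA_real_, B, design$T)
  draws_beta <- matrix(NA_real_, B, design$T)
  fail <- 0L
  for (b in seq_len(B)) {
    set.seed(seed + b)
    idx <- c(if (length(tr_idx)) sample(tr_idx, length(tr_idx), TRUE),
             if (length(wd_idx)) sample(wd_idx, length(wd_idx), TRUE))
    hb <- histories[idx, , drop = FALSE]
    hb$id <- sprintf("bs%05d", seq_along(idx))
    fb <- tryCatch(fit_mle(hb, design, spec, model, refit_opts),
                   error = function(e) NULL)
    if (is.null(fb) || !isTRUE(fb$converged)) { fail <- fail + 1L; next }
    draws_ab[b, ] <- fb$abundance
    draws_N[b] <- sum(vapply(fb$params, function(p) p$N, numeric(1)))
    pr <- fb$params[[1]]
    draws_phi[b, ] <- pr$phi
    draws_p[b, ] <- pr$p
    draws_beta[b, ] <- pr$beta
  }
  if (fail > 0.2 * B)
    stop(sprintf("bootstrap unreliable: %d of %d refits failed", fail, B))
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- function(m) t(apply(m, 2, stats::quantile, probs = qs,
                            na.rm = TRUE, names = FALSE))
  ab <- ci(draws_ab); colnames(ab) <- c("lower", "upper")
  list(level = level, B_used = B - fail, failures = fail, fit = base,
       abundance = ab,
       N = stats::quantile(draws_N[!is.na(draws_ab[, 1])], qs,
                           names = FALSE),
       phi = ci(draws_phi), p = ci(draws_p), beta = ci(draws_beta))
}

#' AIC model selection over candidate specifications
#'
#' Fits every candidate for the chosen model family and ranks them by AIC
#' (`2k - 2 logL`). Fit failures are reported as flagged rows, not errors.
#' Ties are broken by smaller `k`, then by registration order.
#'
#' @param candidates list of [tjs_model_spec()] objects.
#' @inheritParams fit_mle
#' @return data frame sorted ascending by AIC with columns `name`, `k`,
#'   `logLik`, `AIC`, `dAIC`, `converged`; the fitted objects are attached
#'   as the `fits` attribute.
#' @export
aic_select <- function(candidates, histories, design,
                       model = c("translocation", "standard"),
                       options = list()) {
  model <- match.arg(model)
  if (!length(candidates)) stop("need at least one candidate spec")
  fits <- lapply(candidates, function(sp)
    tryCatch(fit_mle(histories, design, sp, model, options),
             error = function(e)
               structure(list(converged = FALSE, message = conditionMessage(e)),
                         class = "tjs_fit")))
  tab <- data.frame(
    name = vapply(seq_along(candidates), function(i)
      candidates[[i]]$name %||% paste0("model", i), character(1)),
    k = vapply(fits, function(f) if (is.null(f$k)) NA_integer_ else f$k,
               integer(1)),
    logLik = vapply(fits, function(f) f$logLik %||% NA_real_, numeric(1)),
    AIC = vapply(fits, function(f) f$AIC %||% NA_real_, numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    stringsAsFactors = FALSE)
  ord <- order(tab$AIC, tab$k, seq_len(nrow(tab)), na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab$dAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  tab
}
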