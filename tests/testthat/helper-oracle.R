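# Brute-force enumeration oracle, independent of the package's likelihood
# core: plain-arithmetic products over the latent (entry, last-alive)
# fates. Used to pin down expected history probabilities and likelihoods
# on small problems.

oracle_prob <- function(x, origin, params, design,
                        model = c("translocation", "standard")) {
  model <- match.arg(model)
  T <- design$T
  phi <- params$phi; p <- params$p; beta <- params$beta
  if (origin == "translocated") p[1] <- 1
  tau <- if (model == "translocation") design$tau else 1L
  f <- which(x == 1)[1]
  dl <- max(which(x == 1))
  bs <- if (origin == "translocated") 1L else tau:f
  total <- 0
  for (b in bs) for (d in dl:T) {
    pr <- if (origin == "translocated") 1 else beta[b]
    if (d > b) for (j in b:(d - 1)) pr <- pr * phi[j]
    if (d < T) pr <- pr * (1 - phi[d])
    for (j in b:d) pr <- pr * (if (x[j] == 1) p[j] else 1 - p[j])
    total <- total + pr
  }
  total
}

oracle_prob_never <- function(params, design,
                              model = c("translocation", "standard")) {
  model <- match.arg(model)
  T <- design$T
  phi <- params$phi; p <- params$p; beta <- params$beta
  tau <- if (model == "translocation") design$tau else 1L
  total <- 0
  for (b in tau:T) for (d in b:T) {
    pr <- beta[b]
    if (d > b) for (j in b:(d - 1)) pr <- pr * phi[j]
    if (d < T) pr <- pr * (1 - phi[d])
    for (j in b:d) pr <- pr * (1 - p[j])
    total <- total + pr
  }
  total
}

oracle_loglik <- function(params, design, histories,
                          model = c("translocation", "standard")) {
  model <- match.arg(model)
  m <- detection_matrix(histories)
  tr <- histories$origin == "translocated"
  Dw <- if (model == "translocation") sum(!tr) else nrow(m)
  ll <- lgamma(params$N + 1) - lgamma(params$N - Dw + 1)
  for (i in seq_len(nrow(m))) {
    orig <- if (model == "translocation" && tr[i]) "translocated"
            else "wild"
    ll <- ll + log(oracle_prob(m[i, ], orig, params, design, model))
  }
  if (params$N - Dw > 0)
    ll <- ll + (params$N - Dw) * log(oracle_prob_never(params, design,
                                                       model))
  ll
}

# All observable binary histories of length T (at least one detection).
all_histories <- function(T) {
  g <- as.matrix(expand.grid(rep(list(0:1), T)))[-1, , drop = FALSE]
  colnames(g) <- NULL
  g[, T:1, drop = FALSE]
}

random_params <- function(T, tau, N = stats::runif(1, 5, 50),
                          standard = FALSE) {
  first_free <- if (standard) 1L else tau
  beta <- numeric(T)
  raw <- stats::runif(T - first_free + 1, 0.2, 1)
  beta[first_free:T] <- raw / sum(raw)
  tjs_params(N = N,
             phi = stats::runif(T - 1, 0.3, 0.95),
             p = stats::runif(T, 0.1, 0.9),
             beta = beta)
}

# Small random dataset guaranteed valid for the translocation model.
random_dataset <- function(T, tau, n_tr = 3, n_wild = 4) {
  det_tr <- matrix(0L, n_tr, T)
  det_tr[, 1] <- 1L
  if (T > 1)
    det_tr[, -1] <- matrix(stats::rbinom(n_tr * (T - 1), 1, 0.5), n_tr)
  det_w <- matrix(0L, n_wild, T)
  for (i in seq_len(n_wild)) {
    f <- sample(rep(tau:T, 2), 1)  # rep() guards the scalar-range case
    det_w[i, f] <- 1L
    if (f < T)
      det_w[i, (f + 1):T] <- stats::rbinom(T - f, 1, 0.5)
  }
  h <- tjs_histories(rbind(det_tr, det_w),
                     origin = c(rep("translocated", n_tr),
                                rep("wild", n_wild)))
  d <- transjs:::derive_design_counts(tjs_design(T, tau = tau), h)
  list(design = d, histories = h)
}
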