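#' Time-lagged independent component analysis
#'
#' Linear projection maximizing autocorrelation at lag tau, exposing the
#' slowest coordinates of a feature trajectory (e.g. backbone-torsion sin/cos
#' features of a loop). The time-lagged covariance is symmetrized and the
#' generalized eigenproblem `C0t v = lambda C00 v` is solved with a small
#' ridge (1e-10) on the instantaneous covariance; components are ordered by
#' descending eigenvalue and are generalized-orthonormal with respect to C00.
#'
#' @param features F x d numeric matrix.
#' @param lag lag time in frames (1 <= lag < F).
#' @return object of class `"tica_model"`: list with `lag`, `mean`,
#'   `eigenvalues`, `components` (d x m eigenvector matrix), `projected`
#'   (F x m tIC coordinates).
#' @export
tica <- function(features, lag) {
  x <- as.matrix(features)
  f <- nrow(x)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1")
  if (f <= lag) stop("need more frames (", f, ") than the lag (", lag, ")")
  if (!all(is.finite(x))) stop("features must be finite")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  x0 <- xc[seq_len(f - lag), , drop = FALSE]
  xt <- xc[(lag + 1L):f, , drop = FALSE]
  n <- f - lag
  c00 <- (crossprod(x0) + crossprod(xt)) / (2 * n)
  c0t <- (crossprod(x0, xt) + crossprod(xt, x0)) / (2 * n)
  eps <- 1e-10
  c00 <- c00 + diag(eps, ncol(x))
  # whiten: C00 = Q L Q'; keep directions with non-negligible variance
  eg <- eigen(c00, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-8
  if (!all(keep)) warning("rank-deficient feature covariance; ",
                          sum(!keep), " direction(s) regularized out")
  L <- eg$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eg$values[keep]), sum(keep))
  m <- t(L) %*% c0t %*% L
  m <- (m + t(m)) / 2
  em <- eigen(m, symmetric = TRUE)
  ord <- order(em$values, decreasing = TRUE)
  comps <- L %*% em$vectors[, ord, drop = FALSE]
  structure(list(lag = lag, mean = mu, eigenvalues = em$values[ord],
                 components = comps, projected = xc %*% comps),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tICA model: lag %d frames, %d components; leading eigenvalues %s\n",
              x$lag, ncol(x$components),
              paste(sprintf("%.3f", utils::head(x$eigenvalues, 3)), collapse = ", ")))
  invisible(x)
}

#' Discretize projected coordinates into microstates by k-means
#'
#' k-means++ seeding with a fixed seed followed by Lloyd iterations
#' (delegated to [stats::kmeans()]), so labels are deterministic given the
#' seed. 150 microstates is the conventional choice for loop kinetics.
#'
#' @param projected F x k matrix of (tIC) coordinates.
#' @param n_states number of microstates (default 150; must be <= F).
#' @param seed integer RNG seed.
#' @return integer vector of per-frame microstate labels (1-based).
#' @export
kmeans_microstates <- function(projected, n_states = 150L, seed = 1L) {
  x <- as.matrix(projected)
  f <- nrow(x)
  n_states <- as.integer(n_states)
  if (n_states > f) stop("n_states (", n_states, ") exceeds frame count (", f, ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  centers <- .kmeanspp_init(x, n_states)
  if (n_states == f) return(max.col(-.sqdist(x, centers), ties.method = "first"))
  km <- suppressWarnings(stats::kmeans(x, centers = centers,
                                       iter.max = 500L, algorithm = "Lloyd"))
  as.integer(km$cluster)
}

.sqdist <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
}

.kmeanspp_init <- function(x, k) {
  f <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(f, 1L)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ])^2)
  for (i in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      idx[i + 1L] <- sample(setdiff(seq_len(f), idx[seq_len(i)]), 1L)
    } else {
      idx[i + 1L] <- sample.int(f, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[i + 1L], ])^2))
  }
  x[idx, , drop = FALSE] + 0  # numeric matrix of initial centers
}

#' Estimate a Markov-state model from discrete trajectories
#'
#' Sliding-window transition counts at lag tau, restricted to the largest
#' strongly connected component of the count graph (states outside it cannot
#' support equilibrium probabilities). With `reversible = TRUE` (default) the
#' counts are symmetrized, (C + C')/2, before row normalization, so detailed
#' balance holds by construction and the stationary distribution is the
#' normalized symmetrized row sum.
#'
#' @param dtrajs integer vector or list of integer vectors (state labels).
#' @param lag lag time in frames.
#' @param reversible logical, default TRUE.
#' @return object of class `"markov_model"`: `lag`, `counts`, `transition`,
#'   `stationary`, `eigenvalues`, `timescales` (frames; `-lag / log(lambda_i)`
#'   for i >= 2, NA where lambda <= 0), `active_set` (original state labels),
#'   `retained_fraction` (fraction of transition counts inside the active
#'   set), `reversible`.
#' @export
estimate_msm <- function(dtrajs, lag, reversible = TRUE) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1")
  states <- sort(unique(unlist(dtrajs)))
  k <- length(states)
  C <- matrix(0, k, k, dimnames = list(states, states))
  total <- 0L
  for (tr in dtrajs) {
    tr <- match(as.integer(tr), states)
    n <- length(tr)
    if (n <= lag) stop("every trajectory must be longer than the lag")
    from <- tr[seq_len(n - lag)]
    to <- tr[(lag + 1L):n]
    tab <- table(factor(from, levels = seq_len(k)), factor(to, levels = seq_len(k)))
    C <- C + as.matrix(tab)
    total <- total + (n - lag)
  }
  g <- igraph::graph_from_adjacency_matrix(C > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  # largest SCC by transition counts observed inside it
  counts_in <- vapply(seq_len(comp$no), function(ci) {
    m <- comp$membership == ci
    sum(C[m, m, drop = FALSE])
  }, numeric(1))
  best <- which.max(counts_in)
  act <- which(comp$membership == best)
  if (!length(act) || counts_in[best] == 0) stop("empty active set at this lag")
  Ca <- C[act, act, drop = FALSE]
  if (reversible) {
    Cs <- (Ca + t(Ca)) / 2
    Tm <- Cs / rowSums(Cs)
    pi_vec <- rowSums(Cs) / sum(Cs)
  } else {
    Tm <- Ca / rowSums(Ca)
    ev <- eigen(t(Tm))
    i1 <- which.max(Re(ev$values))
    pi_vec <- Re(ev$vectors[, i1])
    pi_vec <- pi_vec / sum(pi_vec)
  }
  lam <- eigen(Tm)$values
  lam <- Re(lam[order(-Re(lam))])
  ts <- rep(NA_real_, length(lam) - 1L)
  ok <- lam[-1] > 0 & lam[-1] < 1
  ts[ok] <- -lag / log(lam[-1][ok])
  structure(list(lag = lag, counts = Ca, transition = Tm,
                 stationary = stats::setNames(pi_vec, states[act]),
                 eigenvalues = lam, timescales = ts,
                 active_set = states[act],
                 retained_fraction = counts_in[best] / total,
                 reversible = reversible),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("Markov model: %d states (%.1f%% counts retained), lag %d frames\n",
              length(x$active_set), 100 * x$retained_fraction, x$lag))
  cat(sprintf("  slowest timescale: %s frames\n",
              if (is.na(x$timescales[1])) "undefined" else
                sprintf("%.1f", x$timescales[1])))
  invisible(x)
}

#' Implied timescales across lag times
#'
#' `t_i(tau) = -tau / log(lambda_i(tau))` for i = 2..m; flat curves indicate
#' Markovian behaviour at that lag. Non-positive eigenvalues yield NA.
#'
#' @param dtrajs discrete trajectory (or list).
#' @param lags integer vector of lags.
#' @param n_timescales number of timescales per lag (default 3).
#' @param reversible passed to [estimate_msm()].
#' @return data.frame with columns `lag`, `index`, `timescale`.
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 3L, reversible = TRUE) {
  out <- do.call(rbind, lapply(as.integer(lags), function(l) {
    m <- estimate_msm(dtrajs, l, reversible = reversible)
    ts <- m$timescales[seq_len(min(n_timescales, length(m$timescales)))]
    data.frame(lag = l, index = seq_along(ts) + 1L, timescale = ts)
  }))
  rownames(out) <- NULL
  out
}

#' Coarse-grain microstates into metastable macrostates
#'
#' Crisp spectral assignment in the PCCA style: microstates are clustered by
#' seeded k-means on their coordinates in the first `n_macro` right
#' eigenvectors of the transition matrix, which separates weakly coupled
#' blocks exactly in the metastable regime. Macrostate populations are the
#' summed stationary weights; a coarse transition matrix is obtained by
#' stationary-weighted aggregation.
#'
#' @param model a [estimate_msm()] result (reversible).
#' @param n_macro number of macrostates (2 <= n_macro <= number of states).
#' @param seed RNG seed for the k-means step.
#' @return list with `macro_assignment` (per-microstate macro id),
#'   `macro_populations`, `coarse_transition`, `coarse_timescales` (frames).
#' @export
pcca_macrostates <- function(model, n_macro, seed = 1L) {
  stopifnot(inherits(model, "markov_model"))
  k <- nrow(model$transition)
  n_macro <- as.integer(n_macro)
  if (n_macro > k) stop("n_macro (", n_macro, ") exceeds microstate count (", k, ")")
  if (n_macro < 1L) stop("n_macro must be >= 1")
  eg <- eigen(model$transition)
  ord <- order(-Re(eg$values))
  evec <- Re(eg$vectors[, ord[seq_len(n_macro)], drop = FALSE])
  if (n_macro == k) {
    assign_vec <- seq_len(k)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    # scale eigenvector columns so k-means sees comparable spreads
    sc <- apply(evec, 2, function(cc) if (stats::sd(cc) > 0) cc / stats::sd(cc) else cc)
    km <- suppressWarnings(stats::kmeans(sc, centers = n_macro, nstart = 10L,
                                         iter.max = 100L))
    assign_vec <- as.integer(km$cluster)
  }
  pops <- vapply(seq_len(n_macro), function(a)
    sum(model$stationary[assign_vec == a]), numeric(1))
  # order macrostates by decreasing population for stable ids
  ord_m <- order(-pops)
  relabel <- match(seq_len(n_macro), ord_m)
  assign_vec <- relabel[assign_vec]
  pops <- pops[ord_m]
  Tc <- matrix(0, n_macro, n_macro)
  for (a in seq_len(n_macro)) for (b in seq_len(n_macro)) {
    ia <- assign_vec == a; ib <- assign_vec == b
    wa <- model$stationary[ia]
    Tc[a, b] <- sum(wa * rowSums(model$transition[ia, ib, drop = FALSE])) / sum(wa)
  }
  lam <- Re(eigen(Tc)$values)
  lam <- lam[order(-lam)]
  cts <- rep(NA_real_, max(n_macro - 1L, 0L))
  ok <- lam[-1] > 0 & lam[-1] < 1
  cts[ok] <- -model$lag / log(lam[-1][ok])
  list(macro_assignment = stats::setNames(assign_vec, rownames(model$transition)),
       macro_populations = pops,
       coarse_transition = Tc,
       coarse_timescales = cts)
}

#' Chapman-Kolmogorov test
#'
#' Compares the transition matrix propagated to longer times,
#' `T(tau)^kappa`, with a fresh MSM estimated directly at lag `kappa * tau`,
#' on the common active set. Small deviations across factors support the
#' Markov assumption at lag tau.
#'
#' @param dtrajs discrete trajectory (or list).
#' @param lag base lag in frames.
#' @param factors integer multiples kappa to test (e.g. `c(1, 2, 4)`).
#' @param reversible passed to [estimate_msm()].
#' @return object of class `"ck_test"`: per-factor list with `predicted`,
#'   `estimated`, `max_deviation`; plus the overall `max_deviation`.
#' @export
ck_test <- function(dtrajs, lag, factors = c(1L, 2L, 4L), reversible = TRUE) {
  base <- estimate_msm(dtrajs, lag, reversible = reversible)
  per <- lapply(as.integer(factors), function(kf) {
    est <- estimate_msm(dtrajs, lag * kf, reversible = reversible)
    common <- intersect(base$active_set, est$active_set)
    if (!length(common)) stop("no common active set at factor ", kf)
    ib <- match(common, base$active_set)
    ie <- match(common, est$active_set)
    pred <- .mat_power(base$transition, kf)[ib, ib, drop = FALSE]
    pred <- pred / rowSums(pred)      # renormalize on the common set
    estm <- est$transition[ie, ie, drop = FALSE]
    estm <- estm / rowSums(estm)
    list(factor = kf, predicted = pred, estimated = estm,
         max_deviation = max(abs(pred - estm)))
  })
  structure(list(lag = lag, factors = as.integer(factors), results = per,
                 max_deviation = max(vapply(per, `[[`, numeric(1), "max_deviation"))),
            class = "ck_test")
}

#' @export
print.ck_test <- function(x, ...) {
  cat(sprintf("Chapman-Kolmogorov test at lag %d: max deviation %.4f\n",
              x$lag, x$max_deviation))
  for (r in x$results)
    cat(sprintf("  factor %d: max |predicted - estimated| = %.4f\n",
                r$factor, r$max_deviation))
  invisible(x)
}

.mat_power <- function(m, p) {
  out <- diag(nrow(m))
  base <- m
  while (p > 0) {
    if (p %% 2 == 1) out <- out %*% base
    base <- base %*% base
    p <- p %/% 2
  }
  out
}

#' Simulate a discrete Markov chain
#'
#' Utility for generating ground-truth label sequences from a known
#' transition matrix (used for parameter-recovery checks).
#'
#' @param transition row-stochastic k x k matrix.
#' @param n_steps chain length.
#' @param start initial state (default 1).
#' @param seed optional RNG seed.
#' @return integer vector of states (1-based).
#' @export
simulate_markov_chain <- function(transition, n_steps, start = 1L, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  k <- nrow(transition)
  out <- integer(n_steps)
  out[1] <- as.integer(start)
  u <- stats::runif(n_steps)
  cum <- t(apply(transition, 1, cumsum))
  for (t in 2:n_steps)
    out[t] <- which(u[t] <= cum[out[t - 1L], ])[1]
  out
}
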