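#' Parameter grids for Bayesian psychometric estimation
#'
#' Defaults: sigma from 0.01 to 40.01 mm in steps of 0.05 (801 points,
#' uniform prior), and, for conflict data, mu (the PSE shift) from -5 to
#' +5 mm in steps of 0.1 (101 points, uniform prior).
#'
#' @param from,to,by Grid range and step, mm.
#' @return Strictly increasing numeric vector of grid values.
#' @export
default_sigma_grid <- function(from = 0.01, to = 40.01, by = 0.05) {
  g <- seq(from, to, by = by)
  if (any(g <= 0) || is.unsorted(g, strictly = TRUE))
    stop("sigma grid must be strictly increasing and positive", call. = FALSE)
  g
}

#' @rdname default_sigma_grid
#' @export
default_mu_grid <- function(from = -5, to = 5, by = 0.1) seq(from, to, by = by)

# SD of the difference of two independent percepts in a 2IFC trial: the
# single conversion point between single-interval percept sigma and
# psychometric-function sigma.
TWO_IFC_FACTOR <- sqrt(2)

#' 2IFC psychometric function
#'
#' Probability that the comparison is judged larger at stimulus level
#' `delta`, for a cumulative-normal psychometric function with
#' psychometric sigma `sigma_psy` and PSE shift `mu`:
#' `pnorm((delta - mu) / sigma_psy)`.  `sigma_psy` is on the
#' trial-difference scale; for an observer whose percept SD per interval
#' is `s`, the psychometric sigma is `sqrt(2) * s`.
#'
#' @param delta Comparison minus reference radius, mm (vectorised).
#' @param sigma_psy Psychometric sigma, mm (> 0).
#' @param mu PSE shift, mm (default 0).
#' @return Probability in \[0, 1\].
#' @examples
#' psychometric_prob(2, 2)  # pnorm(1) = 0.841
#' @export
psychometric_prob <- function(delta, sigma_psy, mu = 0) {
  if (!is.numeric(sigma_psy) || anyNA(sigma_psy) || any(sigma_psy <= 0))
    stop("sigma_psy must be positive", call. = FALSE)
  stats::pnorm((delta - mu) / sigma_psy)
}

#' Per-condition 2IFC counts
#'
#' Aggregated binomial data for one condition: at each comparison level
#' `delta`, the number of trials `n` and the number of "comparison judged
#' larger" responses `k`.  (At negative deltas this bookkeeping relates to
#' counts of correct trials by `k <-> n - k`.)
#'
#' @param delta Comparison levels, mm.
#' @param k Comp-judged-larger counts, `0 <= k <= n`.
#' @param n Trial counts, `>= 0`.
#' @return Data frame of class `"condition_data"` sorted by `delta`.
#' @export
condition_data <- function(delta, k, n) {
  if (length(delta) != length(k) || length(k) != length(n))
    stop("delta, k, n must have equal length", call. = FALSE)
  if (anyNA(c(delta, k, n)) || any(k < 0) || any(n < 0) || any(k > n))
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  if (anyDuplicated(delta)) stop("delta levels must be unique", call. = FALSE)
  d <- data.frame(delta = as.numeric(delta), k = as.numeric(k),
                  n = as.numeric(n))
  d <- d[order(d$delta), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("condition_data", "data.frame")
  d
}

condition_data_from_trials <- function(deltas, responses) {
  lev <- sort(unique(deltas))
  k <- vapply(lev, function(d) sum(responses[deltas == d]), numeric(1L))
  n <- vapply(lev, function(d) sum(deltas == d), numeric(1L))
  condition_data(lev, k, n)
}

# Replacement value for a log-likelihood of -Inf (a response that is
# impossible under the parameters): finite so that downstream averaging
# never propagates NaN, yet small enough (log of the smallest subnormal
# double) that it never reorders finite likelihoods.
LOGLIK_FLOOR <- -745

floor_loglik <- function(ll) {
  ll[ll == -Inf] <- LOGLIK_FLOOR
  ll
}

#' Binomial likelihood of condition data
#'
#' Log-likelihood of the counts under a cumulative-normal psychometric
#' function: `sum_k [k log Psi + (n - k) log(1 - Psi)]`.  Binomial
#' coefficients are omitted (constant in the parameters, cancelling in
#' any posterior).  A response that is impossible under the parameters
#' (`Psi` exactly 0 or 1 with a mismatching count) gives likelihood 0,
#' reported as log-likelihood -745 (the log of the smallest subnormal
#' double) rather than `-Inf`, so downstream averages stay finite; finite
#' log-likelihoods are never altered, so orderings are preserved.
#'
#' @param data A [condition_data()] object.
#' @param sigma_psy Psychometric sigma, mm; may be a vector (one
#'   log-likelihood per element).
#' @param mu PSE shift, mm; scalar or vector matching `sigma_psy`.
#' @param log If `FALSE`, return the likelihood on the natural scale.
#' @return Log-likelihood (or likelihood), vectorised over `sigma_psy`.
#' @export
condition_likelihood <- function(data, sigma_psy, mu = 0, log = TRUE) {
  stopifnot(inherits(data, "condition_data"))
  if (any(sigma_psy <= 0)) stop("sigma_psy must be positive", call. = FALSE)
  ll <- floor_loglik(loglik_counts(data$delta, data$k, data$n, sigma_psy,
                                   mu))
  if (log) ll else exp(ll)
}

# Vectorised over parameter vectors sigma_psy (and mu, recycled): returns
# one total log-likelihood per parameter value.  Uses pnorm(log.p = TRUE)
# for stable tails.
loglik_counts <- function(delta, k, n, sigma_psy, mu = 0) {
  np <- max(length(sigma_psy), length(mu))
  if (length(delta) == 0) return(rep(0, np))   # empty product
  sigma_psy <- rep_len(sigma_psy, np)
  mu <- rep_len(mu, np)
  z <- outer(delta, mu, "-") / rep(sigma_psy, each = length(delta))
  lp <- stats::pnorm(z, log.p = TRUE)        # log Psi
  lq <- stats::pnorm(-z, log.p = TRUE)       # log (1 - Psi)
  # 0 * -Inf (no trials or no failures at a saturated level) must give 0
  term <- function(w, l) {
    x <- w * l
    x[w == 0] <- 0
    x
  }
  colSums(term(k, lp) + term(n - k, lq))
}

new_sigma_posterior <- function(grid, prob) {
  structure(list(grid = grid, prob = prob), class = "sigma_posterior")
}

uniform_sigma_posterior <- function(grid = default_sigma_grid()) {
  new_sigma_posterior(grid, rep(1 / length(grid), length(grid)))
}

#' Posterior over the cue sigma from single-cue 2IFC data
#'
#' Grid posterior for the measurement sigma of a single cue, with a
#' uniform prior on the grid.  At each grid value `s` the psychometric
#' sigma is `sqrt(2) * s` (difference of two independent measurements per
#' trial).
#'
#' @param data A [condition_data()] object with at least one trial.
#' @param grid Sigma grid, mm (default [default_sigma_grid()]).
#' @return List of class `"sigma_posterior"` with `grid` and `prob`
#'   (non-negative, summing to 1).
#' @export
sigma_posterior <- function(data, grid = default_sigma_grid()) {
  stopifnot(inherits(data, "condition_data"))
  if (sum(data$n) == 0) return(uniform_sigma_posterior(grid))
  ll <- loglik_counts(data$delta, data$k, data$n, TWO_IFC_FACTOR * grid)
  w <- exp(ll - max(ll))
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0)
    stop("degenerate sigma posterior: data assign zero likelihood to the ",
         "entire grid (deltas ", paste(data$delta, collapse = ", "), ")",
         call. = FALSE)
  new_sigma_posterior(grid, w / tot)
}

#' Inverse-CDF draws from a grid posterior
#'
#' Samples sigma values by drawing uniforms on the posterior CDF ordinate
#' and linearly interpolating to the grid abscissa, so the spread of the
#' draws reflects the full posterior uncertainty (preferable to a point
#' estimate such as the mode).
#'
#' @param posterior A `"sigma_posterior"`.
#' @param n_draws Number of draws (default 1000).
#' @return Numeric vector of sigma draws, mm.
#' @export
sample_sigmas <- function(posterior, n_draws = 1000L) {
  stopifnot(inherits(posterior, "sigma_posterior"), n_draws >= 1L)
  keep <- posterior$prob > 0
  cdf <- cumsum(posterior$prob)[keep]
  vals <- posterior$grid[keep]
  u <- stats::runif(n_draws)
  # inverse CDF through the support points, anchored at (0, first support
  # value) so a point-mass posterior returns that value exactly
  stats::approx(x = c(0, cdf), y = c(vals[1L], vals), xout = u,
                rule = 2, ties = "ordered")$y
}

new_joint_posterior <- function(mu_grid, sigma_grid, prob) {
  structure(list(mu_grid = mu_grid, sigma_grid = sigma_grid, prob = prob),
            class = "joint_posterior")
}

uniform_joint_posterior <- function(mu_grid = default_mu_grid(),
                                    grid = default_sigma_grid()) {
  p <- matrix(1 / (length(mu_grid) * length(grid)),
              nrow = length(mu_grid), ncol = length(grid))
  new_joint_posterior(mu_grid, grid, p)
}

#' Joint posterior over (mu, sigma) from conflict-condition data
#'
#' Grid posterior over the PSE shift mu and the percept sigma for one
#' conflict condition, with independent uniform priors on both grids.
#' The likelihood at `(mu, s)` is the binomial likelihood of the counts
#' under `pnorm((delta - mu) / (sqrt(2) s))`.
#'
#' @param data A [condition_data()] from a conflict condition.
#' @param mu_grid PSE-shift grid, mm (default [default_mu_grid()]).
#' @param sigma_grid Sigma grid, mm (default [default_sigma_grid()]).
#' @return List of class `"joint_posterior"` with `mu_grid`, `sigma_grid`
#'   and matrix `prob` (mu by sigma, summing to 1).
#' @export
joint_posterior <- function(data, mu_grid = default_mu_grid(),
                            sigma_grid = default_sigma_grid()) {
  stopifnot(inherits(data, "condition_data"))
  nm <- length(mu_grid); ns <- length(sigma_grid)
  ll <- matrix(0, nm, ns)
  sp <- TWO_IFC_FACTOR * sigma_grid
  for (i in seq_len(nrow(data))) {
    z <- outer(data$delta[i] - mu_grid, sp, "/")
    if (data$k[i] > 0) ll <- ll + data$k[i] * stats::pnorm(z, log.p = TRUE)
    if (data$n[i] > data$k[i])
      ll <- ll + (data$n[i] - data$k[i]) * stats::pnorm(-z, log.p = TRUE)
  }
  w <- exp(ll - max(ll))
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0)
    stop("degenerate joint posterior: data assign zero likelihood to the ",
         "entire grid", call. = FALSE)
  new_joint_posterior(mu_grid, sigma_grid, w / tot)
}

#' PSE shift estimate from a joint posterior
#'
#' Marginalises the joint posterior over sigma and returns the mode of the
#' mu marginal.  Exact ties are broken toward the smallest `|mu|`.
#'
#' @param joint A `"joint_posterior"`.
#' @return PSE shift estimate, mm.
#' @export
pse_estimate <- function(joint) {
  stopifnot(inherits(joint, "joint_posterior"))
  marg <- rowSums(joint$prob)
  idx <- which(marg == max(marg))
  joint$mu_grid[idx[which.min(abs(joint$mu_grid[idx]))]]
}

#' @export
print.sigma_posterior <- function(x, ...) {
  cat("Grid posterior over sigma:", length(x$grid), "points on [",
      min(x$grid), ",", max(x$grid), "] mm; mode",
      x$grid[which.max(x$prob)], "mm\n")
  invisible(x)
}

#' @export
print.joint_posterior <- function(x, ...) {
  cat("Grid posterior over (mu, sigma):", length(x$mu_grid), "x",
      length(x$sigma_grid), "points; PSE mode", pse_estimate(x), "mm\n")
  invisible(x)
}

posterior_prob_vec <- function(posterior) {
  if (inherits(posterior, "sigma_posterior")) posterior$prob
  else as.vector(posterior$prob)
}

# Response-probability table: P(comp judged larger | grid point, delta)
# for every candidate delta; rows follow posterior_prob_vec() order.
psi_table <- function(posterior, candidates) {
  if (inherits(posterior, "sigma_posterior")) {
    sp <- TWO_IFC_FACTOR * posterior$grid
    vapply(candidates, function(d) stats::pnorm(d / sp),
           numeric(length(sp)))
  } else {
    sp <- TWO_IFC_FACTOR * posterior$sigma_grid
    vapply(candidates,
           function(d) as.vector(stats::pnorm(
             outer(d - posterior$mu_grid, sp, "/"))),
           numeric(length(posterior$mu_grid) * length(posterior$sigma_grid)))
  }
}

entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Expected information gain per candidate given the psi table.
expected_gains <- function(prob, psi) {
  h0 <- entropy(prob)
  vapply(seq_len(ncol(psi)), function(j) {
    w1 <- prob * psi[, j]
    w0 <- prob - w1
    p1 <- sum(w1)
    eh <- 0
    if (p1 > 0) eh <- eh + p1 * entropy(w1 / p1)
    if (p1 < 1) eh <- eh + (1 - p1) * entropy(w0 / (1 - p1))
    h0 - eh
  }, numeric(1L))
}

select_from_table <- function(posterior, psi) {
  gains <- expected_gains(posterior_prob_vec(posterior), psi)
  which.max(gains)   # deterministic tie-break: first listed candidate
}

bayes_update <- function(posterior, psi_col, response) {
  prob <- posterior_prob_vec(posterior)
  w <- prob * if (response) psi_col else 1 - psi_col
  tot <- sum(w)
  if (tot <= 0)
    stop("degenerate posterior update: observed response has probability 0",
         call. = FALSE)
  w <- w / tot
  if (inherits(posterior, "sigma_posterior"))
    new_sigma_posterior(posterior$grid, w)
  else
    new_joint_posterior(posterior$mu_grid, posterior$sigma_grid,
                        matrix(w, length(posterior$mu_grid),
                               length(posterior$sigma_grid)))
}

#' Adaptive stimulus selection by expected information gain
#'
#' Given the current grid posterior (over sigma, or jointly over mu and
#' sigma) and a candidate set of comparison levels, returns the candidate
#' that maximises the expected reduction in posterior entropy, computed
#' exactly on the grid by marginalising over the two possible responses.
#' Ties (including the degenerate case of a point-mass posterior, where
#' every gain is zero) resolve to the first candidate in listed order.
#'
#' @param posterior A `"sigma_posterior"` or `"joint_posterior"`.
#' @param candidates Non-empty numeric vector of candidate deltas, mm.
#' @return The selected delta (an element of `candidates`).
#' @export
select_next_stimulus <- function(posterior, candidates) {
  if (length(candidates) == 0)
    stop("adaptive selection requires a non-empty candidate set",
         call. = FALSE)
  if (!inherits(posterior, c("sigma_posterior", "joint_posterior")))
    stop("posterior must be a sigma_posterior or joint_posterior",
         call. = FALSE)
  psi <- psi_table(posterior, candidates)
  candidates[select_from_table(posterior, psi)]
}

#' Export a posterior as a delimited table
#'
#' Writes `(grid value, probability)` rows — or `(mu, sigma, probability)`
#' for a joint posterior — as CSV for external inspection.
#'
#' @param posterior A `"sigma_posterior"` or `"joint_posterior"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(posterior, path) {
  if (inherits(posterior, "sigma_posterior")) {
    utils::write.csv(data.frame(sigma = posterior$grid,
                                probability = posterior$prob),
                     path, row.names = FALSE)
  } else if (inherits(posterior, "joint_posterior")) {
    utils::write.csv(data.frame(
      mu = rep(posterior$mu_grid, times = length(posterior$sigma_grid)),
      sigma = rep(posterior$sigma_grid, each = length(posterior$mu_grid)),
      probability = as.vector(posterior$prob)), path, row.names = FALSE)
  } else stop("unsupported posterior object", call. = FALSE)
  invisible(path)
}
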