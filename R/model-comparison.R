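#' Sample sigma triplets from three single-cue posteriors
#'
#' One independent inverse-CDF draw per cue posterior yields a triplet;
#' `n` triplets form the Monte Carlo sample over which marginal
#' likelihoods average.
#'
#' @param posteriors Named list of `"sigma_posterior"` objects with
#'   elements `thumb`, `index`, `config` (or in that order).
#' @param n Number of triplets.
#' @return An `n x 3` matrix with columns `thumb`, `index`, `config`.
#' @export
sample_triplets <- function(posteriors, n = 1000L) {
  posteriors <- normalize_posterior_list(posteriors)
  cbind(thumb = sample_sigmas(posteriors$thumb, n),
        index = sample_sigmas(posteriors$index, n),
        config = sample_sigmas(posteriors$config, n))
}

normalize_posterior_list <- function(posteriors) {
  if (length(posteriors) != 3L)
    stop("need three single-cue posteriors (thumb, index, config)",
         call. = FALSE)
  ok <- vapply(posteriors, inherits, logical(1L), what = "sigma_posterior")
  if (!all(ok)) stop("all elements must be sigma_posterior objects",
                     call. = FALSE)
  nm <- names(posteriors)
  if (is.null(nm) || !all(c("thumb", "index", "config") %in% nm))
    names(posteriors) <- c("thumb", "index", "config")
  posteriors[c("thumb", "index", "config")]
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# Log marginal likelihood of combined (non-conflict) data for one model,
# given an n x 3 matrix of sigma triplets.
log_marginal_combined <- function(triplets, data, model) {
  sp <- TWO_IFC_FACTOR * combined_sigma_mat(model, triplets)
  ll <- floor_loglik(loglik_counts(data$delta, data$k, data$n, sp))
  log_mean_exp(ll)
}

# Log marginal likelihood of conflict data (all conflict levels jointly)
# for one model: per triplet, the model predicts a shared percept sigma
# and a PSE shift slope * c at each conflict level c.
log_marginal_conflict <- function(triplets, conflict_data, model) {
  sp <- TWO_IFC_FACTOR * combined_sigma_mat(model, triplets)
  slope <- pse_slope_mat(model, triplets)
  conflicts <- conflict_levels(conflict_data)
  ll <- 0
  for (i in seq_along(conflict_data)) {
    d <- conflict_data[[i]]
    ll <- ll + floor_loglik(
      loglik_counts(d$delta, d$k, d$n, sp, mu = slope * conflicts[i]))
  }
  log_mean_exp(ll)
}

conflict_levels <- function(conflict_data) {
  nm <- names(conflict_data)
  if (is.null(nm)) stop("conflict_data must be named by conflict level ",
                        "(e.g. \"-3\", \"+2\")", call. = FALSE)
  lv <- as.numeric(sub("^Conflict", "", nm))
  if (anyNA(lv)) stop("unparseable conflict levels: ",
                      paste(nm, collapse = ", "), call. = FALSE)
  lv
}

#' Marginal likelihood of combined-condition data under a model
#'
#' Monte Carlo marginal likelihood: sigma triplets are sampled from the
#' three single-cue posteriors, each triplet is mapped through the model's
#' combined-sigma formula, the binomial likelihood of the combined data is
#' evaluated at the predicted psychometric sigma, and the arithmetic mean
#' of the likelihoods over triplets (computed by log-sum-exp) is returned.
#'
#' @param posteriors Three single-cue `"sigma_posterior"` objects (thumb,
#'   index, config).
#' @param data Combined-condition [condition_data()] (non-conflict).
#' @param model One of [model_kinds()].
#' @param n_triplets Number of sampled triplets (default 1000).
#' @param triplets Optional pre-sampled triplet matrix (rows = draws); when
#'   supplied, `n_triplets` is ignored.  Sharing one triplet sample across
#'   models is what the classification pipeline does.
#' @return Log marginal likelihood.
#' @export
marginal_likelihood <- function(posteriors, data, model, n_triplets = 1000L,
                                triplets = NULL) {
  model <- check_model(model)
  stopifnot(inherits(data, "condition_data"))
  if (is.null(triplets)) triplets <- sample_triplets(posteriors, n_triplets)
  log_marginal_combined(triplets, data, model)
}

#' Marginal likelihood of cue-conflict data under a model
#'
#' As [marginal_likelihood()], but each triplet predicts both a combined
#' percept sigma and a PSE shift (`pse_slope(model, triplet) * c`) at
#' every conflict level `c`; the likelihood multiplies across all conflict
#' conditions before averaging over triplets.
#'
#' @inheritParams marginal_likelihood
#' @param conflict_data Named list of [condition_data()], one per conflict
#'   level, names parseable as signed conflict levels (e.g. `"-3"`,
#'   `"Conflict+2"`).
#' @return Log marginal likelihood (joint across conflict levels).
#' @export
conflict_marginal_likelihood <- function(posteriors, conflict_data, model,
                                         n_triplets = 1000L,
                                         triplets = NULL) {
  model <- check_model(model)
  stopifnot(is.list(conflict_data),
            all(vapply(conflict_data, inherits, logical(1L),
                       what = "condition_data")))
  if (is.null(triplets)) triplets <- sample_triplets(posteriors, n_triplets)
  log_marginal_conflict(triplets, conflict_data, model)
}

#' Model posterior probabilities from marginal likelihoods
#'
#' Normalises per-model log marginal likelihoods against a model prior
#' (uniform by default) and reports the argmax classification.  Exact ties
#' are broken in the order OPT > WTA > AVG and flagged.
#'
#' @param log_marginals Named numeric vector of log marginal likelihoods
#'   for `"OPT"`, `"WTA"`, `"AVG"` (any order; `-Inf` allowed).
#' @param prior Model prior probabilities in the same order as
#'   `log_marginals` (default uniform).
#' @return List of class `"model_posterior"`: `prob` (named, sums to 1),
#'   `classification`, `tie` (logical), `log_marginals`.
#' @export
model_posteriors <- function(log_marginals,
                             prior = rep(1 / 3, 3L)) {
  if (is.null(names(log_marginals)))
    names(log_marginals) <- model_kinds()
  log_marginals <- log_marginals[model_kinds()]
  if (anyNA(log_marginals))
    stop("log marginals must be supplied for OPT, WTA and AVG",
         call. = FALSE)
  prior <- rep_len(prior, 3L)
  if (abs(sum(prior) - 1) > 1e-8 || any(prior < 0))
    stop("prior must be a probability vector over the three models",
         call. = FALSE)
  lp <- log_marginals + log(prior)
  if (all(!is.finite(lp)))
    stop("degenerate classification: all model marginal likelihoods are 0",
         call. = FALSE)
  w <- exp(lp - max(lp[is.finite(lp)]))
  w[!is.finite(lp)] <- 0
  prob <- w / sum(w)
  best <- which(prob == max(prob))
  structure(list(prob = prob,
                 classification = model_kinds()[best[1L]],  # OPT > WTA > AVG
                 tie = length(best) > 1L,
                 log_marginals = log_marginals),
            class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  cat("Model posterior:",
      paste(sprintf("%s=%.3f", names(x$prob), x$prob), collapse = " "),
      "->", x$classification, if (x$tie) "(tie)" else "", "\n")
  invisible(x)
}

#' Classify one observer from per-condition data
#'
#' The full single-observer pipeline: single-cue sigma posteriors from the
#' `Thumb`, `Index` and `Config` conditions, one shared sample of sigma
#' triplets, per-model marginal likelihoods of the `Combined` condition
#' (non-conflict) or of all conflict conditions jointly, and the model
#' posterior.
#'
#' @param conditions Named list of [condition_data()].  Must contain
#'   `Thumb`, `Index`, `Config` and either `Combined` or at least one
#'   `Conflict<c>` entry.
#' @param n_triplets Number of sampled sigma triplets (default 1000).
#' @param grid Sigma grid for the single-cue posteriors.
#' @param prior Model prior (default uniform).
#' @return A `"model_posterior"` with attribute `"single_cue_posteriors"`.
#' @export
classify_observer <- function(conditions, n_triplets = 1000L,
                              grid = default_sigma_grid(),
                              prior = rep(1 / 3, 3L)) {
  need <- c("Thumb", "Index", "Config")
  if (!all(need %in% names(conditions)))
    stop("conditions must include Thumb, Index and Config", call. = FALSE)
  posts <- list(thumb = sigma_posterior(conditions$Thumb, grid),
                index = sigma_posterior(conditions$Index, grid),
                config = sigma_posterior(conditions$Config, grid))
  triplets <- sample_triplets(posts, n_triplets)
  conflict_names <- grep("^Conflict", names(conditions), value = TRUE)
  lm <- if (length(conflict_names) > 0) {
    cd <- conditions[conflict_names]
    vapply(model_kinds(), function(m)
      log_marginal_conflict(triplets, cd, m), numeric(1L))
  } else {
    if (!"Combined" %in% names(conditions))
      stop("conditions must include Combined or Conflict<c> data",
           call. = FALSE)
    vapply(model_kinds(), function(m)
      log_marginal_combined(triplets, conditions$Combined, m), numeric(1L))
  }
  out <- model_posteriors(lm, prior)
  attr(out, "single_cue_posteriors") <- posts
  out
}

#' Classification accuracy of the pipeline over a simulated population
#'
#' Draws `n_simulants` observers of a given generating strategy from a
#' population, simulates the full experiment for each, classifies each by
#' marginal likelihood, and tallies the assigned labels.
#'
#' @param strategy Generating strategy, one of [model_kinds()].
#' @param pop A [population_spec()] or built-in name (e.g. `"pop3"`).
#' @param n_simulants Number of simulated observers.
#' @param design An [experiment_design()]; its conditions determine whether
#'   classification uses the `Combined` data or the conflict conditions.
#' @param n_triplets Triplets per marginal likelihood (default 1000).
#' @param grid Sigma grid.
#' @return List of class `"population_run"`: `counts` (named count of
#'   assigned labels, summing to `n_simulants`), `observers` (data frame
#'   with per-observer sigmas, model probabilities, classification and tie
#'   flag), `strategy`, `design`.
#' @export
classify_population <- function(strategy, pop, n_simulants, design,
                                n_triplets = 1000L,
                                grid = default_sigma_grid()) {
  strategy <- check_model(strategy)
  pop <- resolve_population(pop)
  stopifnot(n_simulants >= 1L)
  rows <- vector("list", n_simulants)
  for (i in seq_len(n_simulants)) {
    id <- sprintf("%s_%s_%04d", strategy, pop$name %||% "pop", i)
    sim <- draw_simulant(pop, strategy, id = id)
    res <- tryCatch(
      classify_observer(run_experiment(sim, design)$conditions,
                        n_triplets = n_triplets, grid = grid),
      error = function(e)
        stop("simulant ", id, ": ", conditionMessage(e), call. = FALSE))
    rows[[i]] <- data.frame(
      observer_id = id, strategy = strategy,
      sigma_thumb = unname(sim$sigmas["thumb"]),
      sigma_index = unname(sim$sigmas["index"]),
      sigma_config = unname(sim$sigmas["config"]),
      p_OPT = unname(res$prob["OPT"]), p_WTA = unname(res$prob["WTA"]),
      p_AVG = unname(res$prob["AVG"]),
      classification = res$classification, tie_flag = res$tie)
  }
  observers <- do.call(rbind, rows)
  counts <- vapply(model_kinds(),
                   function(m) sum(observers$classification == m),
                   numeric(1L))
  structure(list(counts = counts, observers = observers,
                 strategy = strategy, design = design),
            class = "population_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
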