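#' Simulant populations
#'
#' A population specifies, for each cue, the mean and standard deviation of
#' the Gaussian distribution from which per-observer cue sigmas are drawn.
#'
#' @param mean_sigma Named or ordered numeric triplet of per-cue mean sigmas
#'   (thumb, index, config), mm, all positive.
#' @param sd_sigma Triplet of per-cue sigma SDs, mm, all non-negative.
#' @param name Optional population label.
#' @return An object of class `"population_spec"`.
#' @seealso [simulant_populations()] for the three built-in populations.
#' @export
population_spec <- function(mean_sigma, sd_sigma, name = NULL) {
  mean_sigma <- as.numeric(mean_sigma); sd_sigma <- as.numeric(sd_sigma)
  if (length(mean_sigma) != 3L || length(sd_sigma) != 3L)
    stop("mean_sigma and sd_sigma must be triplets (thumb, index, config)",
         call. = FALSE)
  if (anyNA(c(mean_sigma, sd_sigma)) || !all(is.finite(c(mean_sigma, sd_sigma))))
    stop("population parameters must be finite", call. = FALSE)
  if (!all(mean_sigma > 0)) stop("mean sigmas must be positive", call. = FALSE)
  if (!all(sd_sigma >= 0)) stop("sigma SDs must be non-negative", call. = FALSE)
  structure(list(mean_sigma = stats::setNames(mean_sigma, c("thumb", "index", "config")),
                 sd_sigma = stats::setNames(sd_sigma, c("thumb", "index", "config")),
                 name = name),
            class = "population_spec")
}

#' Built-in simulant populations
#'
#' Three canonical populations of model observers, distinguished by the
#' relative sigmas of the cues:
#'
#' * `pop1` "exceptional sigma": the configuration cue is far more reliable
#'   than the cutaneous cues (M = 8, 8, 2 mm; S = 2, 2, 1 mm).
#' * `pop2` "similar sigmas": all three cues near 4 mm (S = 0.1 mm).
#' * `pop3` "varied sigmas": M = 7, 6, 3 mm; S = 2, 3, 1 mm — the only
#'   regime in which all three strategies are mutually distinguishable.
#'
#' @return Named list of [population_spec()] objects.
#' @export
simulant_populations <- function() {
  list(
    pop1 = population_spec(c(8, 8, 2), c(2, 2, 1), name = "pop1"),
    pop2 = population_spec(c(4, 4, 4), c(0.1, 0.1, 0.1), name = "pop2"),
    pop3 = population_spec(c(7, 6, 3), c(2, 3, 1), name = "pop3"))
}

resolve_population <- function(pop) {
  if (inherits(pop, "population_spec")) return(pop)
  if (is.character(pop) && length(pop) == 1L) {
    pops <- simulant_populations()
    if (!pop %in% names(pops))
      stop("unknown population '", pop, "'; built-ins are ",
           paste(names(pops), collapse = ", "), call. = FALSE)
    return(pops[[pop]])
  }
  stop("pop must be a population_spec or a built-in population name",
       call. = FALSE)
}

#' Draw a simulant from a population
#'
#' Each cue sigma is drawn independently from Normal(M_cue, S_cue) and
#' truncated below at 0.1 mm (rejection of the lower tail by pmax; the
#' floor is far below any plausible sensory threshold, so the distortion
#' of the population is negligible except for the heaviest lower tails).
#'
#' @param pop A [population_spec()] or built-in population name.
#' @param strategy Generating strategy, one of [model_kinds()].
#' @param id Observer identifier (default `"sim1"`).
#' @return An object of class `"simulant"`: list with `id`, `sigmas`
#'   ([cue_sigmas()]) and `strategy`.
#' @export
draw_simulant <- function(pop, strategy, id = "sim1") {
  pop <- resolve_population(pop)
  strategy <- check_model(strategy)
  s <- pmax(stats::rnorm(3L, pop$mean_sigma, pop$sd_sigma), 0.1)
  structure(list(id = id, sigmas = cue_sigmas(s[1L], s[2L], s[3L]),
                 strategy = strategy),
            class = "simulant")
}

#' Construct a simulant with fixed sigmas
#'
#' @param sigmas A [cue_sigmas()] triplet.
#' @param strategy One of [model_kinds()].
#' @param id Observer identifier.
#' @return A `"simulant"` object.
#' @export
simulant <- function(sigmas, strategy, id = "sim1") {
  structure(list(id = id, sigmas = as_cue_sigmas(sigmas),
                 strategy = check_model(strategy)),
            class = "simulant")
}

#' Cue-conflict stimulus geometry
#'
#' A conflict stimulus is an oval-like object whose horizontal half-width
#' (driving the finger configuration cue) equals the radius of one circle
#' and whose edge curvature (driving the cutaneous cues) equals that of a
#' different circle.  A conflict of `+c` relative to a reference radius `r`
#' gives half-width `r + c` and curvature-equivalent radius `r - c`.
#'
#' @param reference_radius Nominal circular reference radius, mm.
#' @param conflict Signed conflict level, mm; `|conflict|` must be smaller
#'   than `reference_radius`.
#' @return List of class `"conflict_stimulus"` with fields
#'   `reference_radius`, `conflict`, `half_width` (configuration cue mean)
#'   and `curvature_radius` (cutaneous cue mean).
#' @examples
#' make_conflict_stimulus(10, -3)  # half-width 7, curvature radius 13
#' @export
make_conflict_stimulus <- function(reference_radius, conflict) {
  if (!is.numeric(reference_radius) || reference_radius <= 0)
    stop("reference_radius must be positive (mm)", call. = FALSE)
  if (!is.numeric(conflict) || !is.finite(conflict) ||
      abs(conflict) >= reference_radius)
    stop("invalid conflict geometry: |conflict| must be < reference_radius",
         call. = FALSE)
  structure(list(reference_radius = reference_radius, conflict = conflict,
                 half_width = reference_radius + conflict,
                 curvature_radius = reference_radius - conflict),
            class = "conflict_stimulus")
}

#' Draw noisy cue samples for a presented stimulus
#'
#' Each cue is an independent Gaussian measurement.  For a circular disk
#' (`conflict = 0`) all three cues are centred on the disk radius.  For a
#' conflict stimulus the configuration cue is centred on
#' `radius + conflict` (the half-width) and both cutaneous cues on
#' `radius - conflict` (the curvature-equivalent radius).
#'
#' @param sigmas A [cue_sigmas()] triplet.
#' @param radius Nominal stimulus radius, mm.
#' @param conflict Signed conflict level, mm (default 0).
#' @param n Number of sample triplets.
#' @return For `n = 1` a named numeric triplet (thumb, index, config);
#'   otherwise an `n x 3` matrix with those columns.
#' @export
sample_cues <- function(sigmas, radius, conflict = 0, n = 1L) {
  sigmas <- as_cue_sigmas(sigmas)
  if (!is.numeric(radius) || radius <= 0)
    stop("radius must be positive (mm)", call. = FALSE)
  means <- c(thumb = radius - conflict, index = radius - conflict,
             config = radius + conflict)
  m <- cbind(thumb = stats::rnorm(n, means["thumb"], sigmas["thumb"]),
             index = stats::rnorm(n, means["index"], sigmas["index"]),
             config = stats::rnorm(n, means["config"], sigmas["config"]))
  if (n == 1L) m[1L, ] else m
}

condition_labels <- function() c("Thumb", "Index", "Config", "Combined")

# Percept of a stimulus for each row of an n x 3 cue-sample matrix.
# Single-cue conditions use the named cue's raw sample: all three
# strategies degenerate to the same single-cue observer there, which is
# what lets single-cue data estimate sigma_cue independently of strategy.
percepts_for_condition <- function(sim, cues, condition) {
  switch(condition,
    Thumb = cues[, 1L],
    Index = cues[, 2L],
    Config = cues[, 3L],
    {
      switch(sim$strategy,
        WTA = cues[, wta_cue_index(sim$sigmas)],
        AVG = rowMeans(cues),
        OPT = {
          w <- 1 / sim$sigmas^2
          as.vector(cues %*% w) / sum(w)
        })
    })
}

#' Simulate one 2IFC trial
#'
#' Presents a reference stimulus (circular, or a conflict stimulus in
#' conflict conditions) and a circular comparison at `reference + delta`,
#' draws cue samples for both intervals, forms percepts, and reports
#' whether the comparison was perceived as larger.  Exact percept ties
#' (measure zero under continuous noise) are broken by a fair coin.
#'
#' @param sim A [simulant()] object.
#' @param condition One of `"Thumb"`, `"Index"`, `"Config"`, `"Combined"`,
#'   or `"Conflict"` (conflict reference, circular comparison).
#' @param delta Comparison minus nominal reference radius, mm.
#' @param conflict Signed conflict level applied to the reference, mm.
#' @param reference Nominal reference radius, mm (default 10).
#' @return List with `response_comp_larger` (logical) and `correct`
#'   (logical; `NA` for conflict trials, where larger is undefined).
#' @export
simulate_trial <- function(sim, condition, delta, conflict = 0,
                           reference = 10) {
  stopifnot(inherits(sim, "simulant"))
  cond <- match.arg(condition, c(condition_labels(), "Conflict"))
  ref_cues <- sample_cues(sim$sigmas, reference, conflict = conflict, n = 1L)
  comp_cues <- sample_cues(sim$sigmas, reference + delta, conflict = 0, n = 1L)
  key <- if (cond == "Conflict") "Combined" else cond
  p_ref <- percepts_for_condition(sim, rbind(ref_cues), key)
  p_comp <- percepts_for_condition(sim, rbind(comp_cues), key)
  resp <- if (p_comp == p_ref) stats::runif(1L) < 0.5 else p_comp > p_ref
  correct <- if (cond == "Conflict" || delta == 0) NA else resp == (delta > 0)
  list(response_comp_larger = resp, correct = correct)
}

#' Experiment design
#'
#' Describes a 2IFC size-discrimination experiment: a fixed reference
#' radius, a set of circular comparison radii, trials per comparison level,
#' the ordered conditions, and the trial schedule.  The default reproduces
#' the small-disk design: reference 10 mm, comparisons at
#' 5, 8, 9, 9.5, 10.5, 11, 12, 15 mm (deltas -5, -2, -1, -0.5, +0.5, +1,
#' +2, +5), 20 trials per level, method of constant stimuli.
#'
#' @param reference_radius Reference radius, mm.
#' @param comparison_radii Circular comparison radii, mm, all distinct from
#'   the reference.
#' @param trials_per_level Trials at each comparison level (>= 1).
#' @param conditions Ordered condition labels; conflict conditions are
#'   written `"Conflict+3"`, `"Conflict-2"`, etc.
#' @param schedule `"MCS"` (method of constant stimuli) or `"adaptive"`
#'   (entropy-based Bayesian stimulus selection; see
#'   [select_next_stimulus()]).
#' @return List of class `"experiment_design"`.
#' @export
experiment_design <- function(reference_radius = 10,
                              comparison_radii = c(5, 8, 9, 9.5, 10.5, 11, 12, 15),
                              trials_per_level = 20L,
                              conditions = condition_labels(),
                              schedule = c("MCS", "adaptive")) {
  schedule <- match.arg(schedule)
  if (trials_per_level < 1L) stop("trials_per_level must be >= 1", call. = FALSE)
  if (any(comparison_radii == reference_radius))
    stop("comparison radii must be distinct from the reference", call. = FALSE)
  if (any(comparison_radii <= 0) || reference_radius <= 0)
    stop("radii must be positive", call. = FALSE)
  structure(list(reference_radius = reference_radius,
                 comparison_radii = sort(comparison_radii),
                 trials_per_level = as.integer(trials_per_level),
                 conditions = conditions, schedule = schedule),
            class = "experiment_design")
}

#' Conflict variant of a design
#'
#' Convenience wrapper: single-cue conditions followed by one conflict
#' condition per conflict level (default levels -3, -2, +2, +3 mm).
#'
#' @inheritParams experiment_design
#' @param conflicts Signed conflict levels, mm.
#' @return An [experiment_design()].
#' @export
conflict_design <- function(reference_radius = 10,
                            comparison_radii = c(5, 8, 9, 9.5, 10.5, 11, 12, 15),
                            trials_per_level = 20L,
                            conflicts = c(-3, -2, 2, 3),
                            schedule = "MCS") {
  experiment_design(reference_radius, comparison_radii, trials_per_level,
                    conditions = c("Thumb", "Index", "Config",
                                   sprintf("Conflict%+g", conflicts)),
                    schedule = schedule)
}

parse_condition <- function(label) {
  if (grepl("^Conflict", label)) {
    c_val <- as.numeric(sub("^Conflict", "", label))
    if (is.na(c_val)) stop("malformed conflict condition label: ", label,
                           call. = FALSE)
    list(kind = "Conflict", conflict = c_val)
  } else {
    list(kind = match.arg(label, condition_labels()), conflict = 0)
  }
}

# Vectorised simulation of one condition under the MCS schedule: returns a
# logical response vector aligned with `deltas`.
simulate_condition_responses <- function(sim, condition, deltas, conflict,
                                         reference) {
  n <- length(deltas)
  key <- if (condition == "Conflict") "Combined" else condition
  ref_cues <- sample_cues(sim$sigmas, reference, conflict = conflict, n = n)
  comp_cues <- cbind(
    thumb = stats::rnorm(n, reference + deltas, sim$sigmas["thumb"]),
    index = stats::rnorm(n, reference + deltas, sim$sigmas["index"]),
    config = stats::rnorm(n, reference + deltas, sim$sigmas["config"]))
  p_ref <- percepts_for_condition(sim, ref_cues, key)
  p_comp <- percepts_for_condition(sim, comp_cues, key)
  resp <- p_comp > p_ref
  ties <- p_comp == p_ref
  if (any(ties)) resp[ties] <- stats::runif(sum(ties)) < 0.5
  resp
}

#' Run a full 2IFC experiment for one simulant
#'
#' Simulates every condition of a design and aggregates responses into
#' per-condition counts of "comparison judged larger" at each delta.
#' Under `"MCS"` each comparison level is presented `trials_per_level`
#' times in randomised order; under `"adaptive"` each trial's comparison
#' is chosen to maximise expected information gain about the psychometric
#' parameters, with the same total trial budget.
#'
#' @param sim A [simulant()].
#' @param design An [experiment_design()].
#' @param keep_trials If `TRUE`, also return the trial-level log (one row
#'   per trial, in presentation order).
#' @return List of class `"experiment_data"`: `observer` (the simulant),
#'   `design`, `conditions` (named list of [condition_data()] keyed by
#'   condition label), and `trials` (data frame, or `NULL`).
#' @export
run_experiment <- function(sim, design, keep_trials = FALSE) {
  stopifnot(inherits(sim, "simulant"), inherits(design, "experiment_design"))
  deltas_all <- design$comparison_radii - design$reference_radius
  out <- vector("list", length(design$conditions))
  names(out) <- design$conditions
  trial_rows <- if (keep_trials) vector("list", length(design$conditions))
  for (i in seq_along(design$conditions)) {
    label <- design$conditions[[i]]
    info <- parse_condition(label)
    if (info$kind == "Conflict")  # validate the geometry once per condition
      make_conflict_stimulus(design$reference_radius, info$conflict)
    if (design$schedule == "MCS") {
      deltas <- sample(rep(deltas_all, each = design$trials_per_level))
      resp <- simulate_condition_responses(sim, info$kind, deltas,
                                           info$conflict,
                                           design$reference_radius)
    } else {
      run <- run_adaptive_condition(sim, info, design)
      deltas <- run$deltas
      resp <- run$responses
    }
    out[[label]] <- condition_data_from_trials(deltas, resp)
    if (keep_trials) {
      trial_rows[[i]] <- data.frame(
        observer_id = sim$id, strategy = sim$strategy, condition = label,
        conflict_mm = info$conflict, reference_mm = design$reference_radius,
        comparison_mm = design$reference_radius + deltas, delta_mm = deltas,
        response_comp_larger = resp,
        block = i, trial_index = seq_along(deltas))
    }
  }
  structure(list(observer = sim, design = design, conditions = out,
                 trials = if (keep_trials) do.call(rbind, trial_rows)),
            class = "experiment_data")
}

# Adaptive schedule for one condition: greedy entropy-gain selection on the
# sigma grid (single-cue and combined conditions) or the (mu, sigma) grid
# (conflict conditions), with the design's deltas as the candidate set.
run_adaptive_condition <- function(sim, info, design,
                                   grid = default_sigma_grid()) {
  candidates <- design$comparison_radii - design$reference_radius
  n_total <- design$trials_per_level * length(candidates)
  joint <- info$kind == "Conflict"
  post <- if (joint) uniform_joint_posterior(grid = grid)
          else uniform_sigma_posterior(grid)
  psi <- psi_table(post, candidates)   # grid x candidate response probs
  deltas <- numeric(n_total)
  responses <- logical(n_total)
  for (t in seq_len(n_total)) {
    j <- select_from_table(post, psi)
    deltas[t] <- candidates[j]
    tr <- simulate_trial(sim, if (joint) "Conflict" else info$kind,
                         deltas[t], conflict = info$conflict,
                         reference = design$reference_radius)
    responses[t] <- tr$response_comp_larger
    post <- bayes_update(post, psi[, j], responses[t])
  }
  list(deltas = deltas, responses = responses)
}
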