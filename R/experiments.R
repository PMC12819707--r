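#' Run configuration
#'
#' Fully specifies a population-level simulation run: which population
#' generates the observers, which strategies generate data, the experiment
#' design, Monte Carlo sizes, and the master seed.  The master seed spawns
#' one child seed per (strategy, simulant-batch) via `sample.int`, recorded
#' in the report metadata, so runs are reproducible end to end.
#'
#' @param population A [population_spec()] or built-in name
#'   (default `"pop3"`, the varied-sigma population under which the three
#'   strategies are mutually distinguishable).
#' @param strategies Generating strategies to run (default all three).
#' @param design An [experiment_design()]; `NULL` selects the default
#'   non-conflict design, or the default [conflict_design()] when
#'   `conflict = TRUE`.
#' @param conflict Use the cue-conflict design?
#' @param n_simulants Observers per generating strategy (default 1000).
#' @param n_triplets Sigma triplets per marginal likelihood (default 1000).
#' @param seed Master seed (integer).
#' @param output_dir Optional directory for trial logs and reports; `NULL`
#'   keeps everything in memory.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(population = "pop3",
                       strategies = model_kinds(),
                       design = NULL,
                       conflict = FALSE,
                       n_simulants = 1000L,
                       n_triplets = 1000L,
                       seed = 1L,
                       output_dir = NULL) {
  population <- resolve_population(population)
  strategies <- vapply(strategies, check_model, character(1L))
  if (is.null(design))
    design <- if (conflict) conflict_design() else experiment_design()
  stopifnot(inherits(design, "experiment_design"),
            n_simulants >= 1L, n_triplets >= 1L)
  has_conflict <- any(grepl("^Conflict", design$conditions))
  if (conflict && !has_conflict)
    stop("conflict = TRUE but the design has no Conflict conditions",
         call. = FALSE)
  structure(list(population = population, strategies = unname(strategies),
                 design = design, conflict = has_conflict,
                 n_simulants = as.integer(n_simulants),
                 n_triplets = as.integer(n_triplets),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognised top-level keys (all optional): `population` (built-in name,
#' or a mapping with `mean_sigma` and `sd_sigma` triplets), `strategies`,
#' `design` (`reference_radius`, `comparison_radii`, `trials_per_level`,
#' `schedule`, `conflicts`), `conflict`, `n_simulants`, `n_triplets`,
#' `seed`, `output_dir`.  Omitted keys take [run_config()] defaults, which
#' reproduce the built-in populations and the small-disk stimulus set.
#'
#' @param path YAML file path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pop <- cfg$population %||% "pop3"
  if (is.list(pop))
    pop <- population_spec(unlist(pop$mean_sigma), unlist(pop$sd_sigma),
                           name = pop$name %||% "custom")
  conflict <- isTRUE(cfg$conflict) || !is.null(cfg$design$conflicts)
  design <- if (is.null(cfg$design)) NULL else {
    d <- cfg$design
    args <- list(
      reference_radius = d$reference_radius %||% 10,
      comparison_radii = unlist(d$comparison_radii) %||%
        c(5, 8, 9, 9.5, 10.5, 11, 12, 15),
      trials_per_level = d$trials_per_level %||% 20L,
      schedule = d$schedule %||% "MCS")
    if (conflict) {
      args$conflicts <- unlist(d$conflicts) %||% c(-3, -2, 2, 3)
      do.call(conflict_design, args)
    } else do.call(experiment_design, args)
  }
  run_config(population = pop,
             strategies = unlist(cfg$strategies) %||% model_kinds(),
             design = design, conflict = conflict,
             n_simulants = cfg$n_simulants %||% 1000L,
             n_triplets = cfg$n_triplets %||% 1000L,
             seed = cfg$seed %||% 1L,
             output_dir = cfg$output_dir)
}

run_population_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L,
                            length(config$strategies))
  names(child_seeds) <- config$strategies
  runs <- vector("list", length(config$strategies))
  names(runs) <- config$strategies
  for (s in config$strategies) {
    set.seed(child_seeds[[s]])
    runs[[s]] <- classify_population(
      s, config$population, config$n_simulants, config$design,
      n_triplets = config$n_triplets)
  }
  confusion <- vapply(runs, function(r) r$counts,
                      numeric(length(model_kinds())))
  rownames(confusion) <- model_kinds()   # rows: assigned classification
  observers <- do.call(rbind, lapply(runs, function(r) r$observers))
  rownames(observers) <- NULL
  report <- structure(list(confusion = confusion, observers = observers,
                           config = config, child_seeds = child_seeds),
                      class = "run_report")
  if (!is.null(config$output_dir)) write_run_report(report)
  report
}

#' Non-conflict classification study
#'
#' Simulates `n_simulants` observers per generating strategy in the
#' four-condition (Thumb, Index, Config, Combined) design and classifies
#' each by the marginal likelihood of its Combined data, producing the
#' 3x3 confusion table (rows = assigned label, columns = generating
#' strategy).
#'
#' @param config A [run_config()]; `NULL` uses defaults (pop3, 1000
#'   simulants and triplets, seed 1).
#' @return List of class `"run_report"`: `confusion`, `observers` (one row
#'   per simulant with sigmas and model posteriors), `config`,
#'   `child_seeds`.
#' @export
run_table1 <- function(config = NULL) {
  config <- config %||% run_config()
  if (config$conflict)
    stop("run_table1 requires a non-conflict design", call. = FALSE)
  run_population_study(config)
}

#' Cue-conflict classification study
#'
#' As [run_table1()] but with the conflict design (single-cue blocks plus
#' one block per conflict level, default levels -3, -2, +2, +3 mm);
#' classification uses the joint (PSE shift, sigma) marginal likelihood of
#' all conflict conditions.  The report additionally carries per-simulant
#' PSE estimates per conflict level and the per-model predicted PSE lines
#' for a subsample of observers.
#'
#' @param config A [run_config()] with a conflict design; `NULL` uses
#'   defaults.
#' @param pse_sample Number of observers (per strategy) for which
#'   Bayesian per-conflict PSE estimates are computed (default 20; the
#'   joint-grid estimate is the costly step and a subsample suffices for
#'   the PSE-versus-conflict summary).
#' @return A `"run_report"` with an extra element `pse` (data frame:
#'   observer, strategy, conflict, PSE estimate, per-model prediction).
#' @export
run_table2 <- function(config = NULL, pse_sample = 20L) {
  config <- config %||% run_config(conflict = TRUE)
  if (!config$conflict)
    stop("run_table2 requires a design with Conflict conditions",
         call. = FALSE)
  report <- run_population_study(config)
  report$pse <- pse_table(report, pse_sample)
  if (!is.null(config$output_dir))
    utils::write.csv(report$pse,
                     file.path(config$output_dir, "pse_by_conflict.csv"),
                     row.names = FALSE)
  report
}

# PSE-versus-conflict table for a subsample of simulants: Bayesian PSE
# estimate per conflict level plus each model's predicted shift from the
# simulant's true sigmas (the Fig. 2C-style analogue).
pse_table <- function(report, pse_sample) {
  config <- report$config
  conflicts <- as.numeric(sub("^Conflict", "",
                              grep("^Conflict", config$design$conditions,
                                   value = TRUE)))
  set.seed(report$child_seeds[[1L]] %% 1000003L + 7L)
  rows <- list()
  for (s in config$strategies) {
    obs <- report$observers[report$observers$strategy == s, , drop = FALSE]
    take <- utils::head(seq_len(nrow(obs)), pse_sample)
    for (i in take) {
      sim <- simulant(c(obs$sigma_thumb[i], obs$sigma_index[i],
                        obs$sigma_config[i]), s, id = obs$observer_id[i])
      dat <- run_experiment(sim, config$design)
      for (cf in conflicts) {
        d <- dat$conditions[[sprintf("Conflict%+g", cf)]]
        jp <- joint_posterior(d)
        rows[[length(rows) + 1L]] <- data.frame(
          observer_id = sim$id, strategy = s, conflict = cf,
          pse = pse_estimate(jp),
          pred_OPT = conflict_pse("OPT", sim$sigmas, cf),
          pred_WTA = conflict_pse("WTA", sim$sigmas, cf),
          pred_AVG = conflict_pse("AVG", sim$sigmas, cf))
      }
    }
  }
  do.call(rbind, rows)
}

write_run_report <- function(report) {
  dir <- report$config$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(report$confusion),
                   file.path(dir, "confusion.csv"))
  utils::write.csv(report$observers, file.path(dir, "observers.csv"),
                   row.names = FALSE)
  cfg <- report$config
  yaml::write_yaml(list(
    population = cfg$population$name %||% "custom",
    strategies = cfg$strategies,
    design = list(reference_radius = cfg$design$reference_radius,
                  comparison_radii = cfg$design$comparison_radii,
                  trials_per_level = cfg$design$trials_per_level,
                  conditions = cfg$design$conditions,
                  schedule = cfg$design$schedule),
    n_simulants = cfg$n_simulants, n_triplets = cfg$n_triplets,
    seed = cfg$seed,
    child_seeds = as.list(report$child_seeds)),
    file.path(dir, "config.yml"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Classification study:", x$config$n_simulants, "simulants per",
      "strategy,", if (x$config$conflict) "conflict" else "non-conflict",
      "design\n\nConfusion (rows = assigned, cols = generating):\n")
  print(x$confusion)
  invisible(x)
}

#' Analyze a trial-log dataset
#'
#' Drop-in analysis of a CSV trial log (synthetic or human origin): pools
#' each observer's trials across blocks, fits single-cue sigma posteriors,
#' classifies each observer by marginal likelihood (combined or conflict,
#' depending on which conditions are present), and summarises sigma
#' estimates per condition.
#'
#' @param path Trial-log CSV path (schema of [write_trial_log()]).
#' @param n_triplets Triplets per marginal likelihood (default 1000).
#' @param grid Sigma grid.
#' @return List of class `"dataset_report"`: `observers` (per-observer
#'   model probabilities and classification), `sigma_summary` (posterior
#'   sigma mode per observer and condition, with across-observer mean and
#'   SE per condition in `attr(,"condition_means")`), `n_skipped`.
#' @export
analyze_dataset <- function(path, n_triplets = 1000L,
                            grid = default_sigma_grid()) {
  log <- read_trial_log(path)
  rows <- list(); sigma_rows <- list(); skipped <- character(0)
  for (id in unique(log$observer_id)) {
    conds <- condition_data_from_log(log[log$observer_id == id, ,
                                         drop = FALSE])
    has_target <- "Combined" %in% names(conds) ||
      any(grepl("^Conflict", names(conds)))
    if (!all(c("Thumb", "Index", "Config") %in% names(conds)) ||
        !has_target) {
      warning("observer ", id, " skipped: missing required condition(s)",
              call. = FALSE)
      skipped <- c(skipped, id)
      next
    }
    res <- classify_observer(conds, n_triplets = n_triplets, grid = grid)
    posts <- attr(res, "single_cue_posteriors")
    rows[[id]] <- data.frame(
      observer_id = id,
      p_OPT = unname(res$prob["OPT"]), p_WTA = unname(res$prob["WTA"]),
      p_AVG = unname(res$prob["AVG"]),
      classification = res$classification, tie_flag = res$tie)
    sigma_rows[[id]] <- data.frame(
      observer_id = id, condition = c("Thumb", "Index", "Config"),
      sigma_mode = vapply(posts, function(p) p$grid[which.max(p$prob)],
                          numeric(1L)))
  }
  if (length(rows) == 0)
    stop("no analyzable observers in ", path, call. = FALSE)
  observers <- do.call(rbind, rows); rownames(observers) <- NULL
  sigma_summary <- do.call(rbind, sigma_rows); rownames(sigma_summary) <- NULL
  means <- do.call(rbind, lapply(split(sigma_summary, sigma_summary$condition),
    function(d) data.frame(condition = d$condition[1L],
                           mean_sigma = mean(d$sigma_mode),
                           se_sigma = stats::sd(d$sigma_mode) /
                             sqrt(nrow(d)))))
  rownames(means) <- NULL
  attr(sigma_summary, "condition_means") <- means
  structure(list(observers = observers, sigma_summary = sigma_summary,
                 n_skipped = length(skipped)),
            class = "dataset_report")
}
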