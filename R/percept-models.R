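#' Perceptual strategies for haptic size judgment
#'
#' Three hypotheses about how an observer forms a single size percept from
#' the thumb cutaneous cue, the index-finger cutaneous cue, and the finger
#' configuration (proprioceptive) cue:
#'
#' * `"WTA"` (winner-take-all): the percept is the sample of the single most
#'   reliable cue (the one with the smallest sigma).
#' * `"AVG"`: the percept is the unweighted arithmetic mean of the three
#'   cue samples.
#' * `"OPT"`: the percept is the inverse-variance (reliability) weighted
#'   mean of the three cue samples, the statistically optimal combination
#'   of independent Gaussian cues.
#'
#' All strategies are unbiased; they differ in the across-trial variability
#' of the percept and in how the percept responds to cue-conflict stimuli.
#'
#' @name percept_models
#' @keywords internal
NULL

#' Model labels in canonical order
#'
#' @return Character vector `c("OPT", "WTA", "AVG")`.
#' @export
model_kinds <- function() c("OPT", "WTA", "AVG")

#' Cue sigma triplet
#'
#' Constructs a validated triplet of per-cue measurement standard
#' deviations, in mm of disk radius.
#'
#' @param thumb,index,config Positive finite standard deviations (mm).
#' @return A named numeric vector of class `"cue_sigmas"` with elements
#'   `thumb`, `index`, `config`.
#' @examples
#' cue_sigmas(7, 6, 3)
#' @export
cue_sigmas <- function(thumb, index, config) {
  s <- c(thumb = as.numeric(thumb), index = as.numeric(index),
         config = as.numeric(config))
  if (length(s) != 3L || anyNA(s) || !all(is.finite(s)) || !all(s > 0))
    stop("cue sigmas must be three strictly positive finite values (mm)",
         call. = FALSE)
  structure(s, class = "cue_sigmas")
}

as_cue_sigmas <- function(x) {
  if (inherits(x, "cue_sigmas")) return(x)
  x <- as.numeric(x)
  if (length(x) != 3L)
    stop("expected a triplet of cue sigmas (thumb, index, config)",
         call. = FALSE)
  cue_sigmas(x[1L], x[2L], x[3L])
}

check_model <- function(model) {
  model <- match.arg(toupper(model), model_kinds())
  model
}

# Index of the winner-take-all cue: the minimum-sigma cue, ties broken by
# the fixed priority order config > index > thumb.
wta_cue_index <- function(sigmas) {
  priority <- c(3L, 2L, 1L)   # config, index, thumb
  priority[which.min(sigmas[priority])]
}

#' Trial-level percept under a perceptual strategy
#'
#' Applies one of the three strategies to a single triplet of noisy cue
#' samples.  `WTA` returns the sample of the minimum-sigma cue (ties broken
#' config > index > thumb), `AVG` the arithmetic mean, and `OPT` the
#' inverse-variance weighted mean.
#'
#' @param model One of `"OPT"`, `"WTA"`, `"AVG"`.
#' @param cues Numeric triplet of cue samples (thumb, index, config), in mm.
#'   Samples may be negative under large noise; they are not clipped.
#' @param sigmas A [cue_sigmas()] triplet.
#' @return The percept, in mm.
#' @examples
#' percept("OPT", c(10, 10, 16), cue_sigmas(8, 8, 2))  # 15.333...
#' @export
percept <- function(model, cues, sigmas) {
  model <- check_model(model)
  sigmas <- as_cue_sigmas(sigmas)
  cues <- as.numeric(cues)
  if (length(cues) != 3L || anyNA(cues) || !all(is.finite(cues)))
    stop("cue samples must be three finite values", call. = FALSE)
  switch(model,
    WTA = cues[wta_cue_index(sigmas)],
    AVG = mean(cues),
    OPT = {
      w <- 1 / sigmas^2
      sum(w * cues) / sum(w)
    })
}

#' Across-trial standard deviation of the percept
#'
#' Closed-form SD of the percept when the same disk is felt repeatedly:
#' `WTA` gives the minimum cue sigma, `AVG` gives
#' \eqn{\sqrt{\sigma_T^2+\sigma_I^2+\sigma_C^2}/3}, and `OPT` gives
#' \eqn{1/\sqrt{1/\sigma_T^2+1/\sigma_I^2+1/\sigma_C^2}}.  The `OPT`
#' percept is always at least as precise as the best single cue.
#'
#' @inheritParams percept
#' @return The percept standard deviation (mm), on the single-interval
#'   scale (see [psychometric_prob()] for the 2IFC conversion).
#' @examples
#' combined_sigma("OPT", cue_sigmas(7, 6, 3))  # 2.5056
#' @export
combined_sigma <- function(model, sigmas) {
  model <- check_model(model)
  sigmas <- as_cue_sigmas(sigmas)
  switch(model,
    WTA = unname(min(sigmas)),
    AVG = sqrt(sum(sigmas^2)) / 3,
    OPT = 1 / sqrt(sum(1 / sigmas^2)))
}

#' Predicted slope of PSE shift versus cue conflict
#'
#' A conflict stimulus of level `c` (mm) presents a configuration cue
#' centred `c` mm above, and cutaneous cues centred `c` mm below, the
#' nominal reference radius.  Each strategy predicts that the point of
#' subjective equality (PSE) shifts linearly in `c`; this returns the
#' dimensionless slope.
#'
#' * `WTA`: +1 when the configuration cue is the most reliable; -1 when a
#'   cutaneous cue wins (its mean moves opposite to the conflict).
#' * `AVG`: -1/3 (two cutaneous cues outvote the configuration cue).
#' * `OPT`: \eqn{(1/\sigma_C^2 - 1/\sigma_I^2 - 1/\sigma_T^2) /
#'   (1/\sigma_T^2 + 1/\sigma_I^2 + 1/\sigma_C^2)}, always in (-1, +1),
#'   strictly increasing in configuration-cue reliability.
#'
#' @inheritParams percept
#' @return Dimensionless slope (mm PSE shift per mm of conflict).
#' @examples
#' pse_slope("AVG", cue_sigmas(7, 6, 3))  # -1/3
#' pse_slope("OPT", cue_sigmas(7, 6, 3))  # 0.395
#' @export
pse_slope <- function(model, sigmas) {
  model <- check_model(model)
  sigmas <- as_cue_sigmas(sigmas)
  switch(model,
    WTA = if (wta_cue_index(sigmas) == 3L) 1 else -1,
    AVG = -1 / 3,
    OPT = {
      w <- 1 / sigmas^2
      unname((w["config"] - w["index"] - w["thumb"]) / sum(w))
    })
}

#' Predicted PSE shift for a cue-conflict stimulus
#'
#' Expected difference between the percept of a conflict reference and the
#' percept of a circular reference of the same nominal radius,
#' `pse_slope(model, sigmas) * conflict`.
#'
#' @inheritParams percept
#' @param conflict Signed conflict level in mm (positive = configuration
#'   cue larger, cutaneous cues smaller).
#' @return Expected PSE shift in mm.
#' @examples
#' conflict_pse("AVG", cue_sigmas(7, 6, 3), 3)  # -1
#' @export
conflict_pse <- function(model, sigmas, conflict) {
  if (!is.numeric(conflict) || anyNA(conflict) || !all(is.finite(conflict)))
    stop("conflict must be a finite numeric value (mm)", call. = FALSE)
  pse_slope(model, sigmas) * conflict
}

# Vectorised internals over an n x 3 matrix of sigma triplets
# (columns thumb, index, config); used by the marginal-likelihood code.

combined_sigma_mat <- function(model, triplets) {
  switch(model,
    WTA = apply(triplets, 1L, min),
    AVG = sqrt(rowSums(triplets^2)) / 3,
    OPT = 1 / sqrt(rowSums(1 / triplets^2)))
}

pse_slope_mat <- function(model, triplets) {
  switch(model,
    # per-triplet re-evaluation of the winning cue; priority config > index
    # > thumb on exact ties, matching wta_cue_index()
    WTA = ifelse(triplets[, 3L] <= pmin(triplets[, 1L], triplets[, 2L]),
                 1, -1),
    AVG = rep(-1 / 3, nrow(triplets)),
    OPT = {
      w <- 1 / triplets^2
      (w[, 3L] - w[, 2L] - w[, 1L]) / rowSums(w)
    })
}
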