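# run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Define a synthetic isotopologue timecourse scenario
#'
#' A scenario states, for each labeled subunit state, a saturating-rise
#' trajectory `b (1 - exp(-k max(0, t - lag)))` for its mole fraction; the
#' subunit's unlabeled (lowest-label) state takes the closure remainder.
#' This emulates a tracer switch at `t = 0`: precursor pools label at
#' different rates, and states requiring more enzymatic steps start rising
#' only after a lag.
#'
#' @param space a [moiety_space()].
#' @param trajectories named list (by subunit name) of named lists (by state
#'   parameter name) of `list(b=, k=, lag=0)` rise parameters. States
#'   without a trajectory stay at zero; the lowest-label state must not be
#'   given one (it is the closure remainder).
#' @param timepoints sampling times in hours (default the 7-point design
#'   `0, 3, 6, 11, 24, 34, 48`).
#' @param noise relative (multiplicative Gaussian) intensity noise sd
#'   (default 0.01, i.e. 1% precision).
#' @param include_natural_abundance convolve profiles with the natural 13C
#'   abundance envelope (default `TRUE`).
#' @param p13 natural 13C abundance (default 0.011).
#' @param seed integer seed making the dataset reproducible.
#' @return a list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(space, trajectories,
                                timepoints = c(0, 3, 6, 11, 24, 34, 48),
                                noise = 0.01,
                                include_natural_abundance = TRUE,
                                p13 = 0.011, seed = 1L) {
  stopifnot(inherits(space, "moiety_space"))
  timepoints <- as.numeric(timepoints)
  if (any(timepoints < 0) || any(diff(timepoints) <= 0))
    stop("timepoints must be non-negative and strictly increasing",
         call. = FALSE)
  if (noise < 0) stop("noise must be non-negative", call. = FALSE)
  sub_names <- vapply(space$subunits, `[[`, character(1), "name")
  unknown <- setdiff(names(trajectories), sub_names)
  if (length(unknown))
    stop("trajectories name unknown subunits: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (su in space$subunits) {
    tr <- trajectories[[su$name]]
    if (is.null(tr)) next
    base_state <- su$parameter_names[1L]  # lowest label: closure remainder
    if (base_state %in% names(tr))
      stop(sprintf("subunit '%s': state '%s' is the closure remainder and takes no trajectory",
                   su$name, base_state), call. = FALSE)
    bad <- setdiff(names(tr), su$parameter_names)
    if (length(bad))
      stop(sprintf("subunit '%s': unknown state(s) %s", su$name,
                   paste(bad, collapse = ", ")), call. = FALSE)
    btot <- sum(vapply(tr, function(x) x$b, numeric(1)))
    if (btot > 1 + 1e-9)
      stop(sprintf("subunit '%s': labeled plateaus sum to %.3f > 1 (closure violated)",
                   su$name, btot), call. = FALSE)
  }
  structure(list(space = space, trajectories = trajectories,
                 timepoints = timepoints, noise = noise,
                 include_natural_abundance = isTRUE(include_natural_abundance),
                 p13 = p13, seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' Default UDP-GlcNAc labeling scenario
#'
#' A parametric stand-in for the experimental FT-ICR-MS timecourse:
#' ribose labels fastest (plateau 0.89, k = 0.13/h, no lag), glucose
#' plateaus above 0.9 after a ~10 h lag, and the acetyl and multi-labeled
#' uracil states rise more slowly with lags that grow with the number of
#' 13C atoms (more enzymatic steps to traverse). Plateaus approximate the
#' late-timecourse component levels: glucose and ribose above 0.9, acetyl
#' near 0.3, and uracil single/double/triple labels near 0.19/0.49/0.16.
#'
#' @inheritParams simulation_scenario
#' @return a `simulation_scenario` for [udp_glcnac_space()].
#' @export
default_scenario <- function(noise = 0.01, include_natural_abundance = TRUE,
                             seed = 1L) {
  simulation_scenario(
    udp_glcnac_space(),
    trajectories = list(
      glucose = list(g6 = list(b = 0.92, k = 0.15, lag = 10)),
      ribose  = list(r5 = list(b = 0.93, k = 0.13, lag = 0)),
      acetyl  = list(a2 = list(b = 0.32, k = 0.08, lag = 4)),
      uracil  = list(u1 = list(b = 0.19, k = 0.10, lag = 3),
                     u2 = list(b = 0.49, k = 0.09, lag = 6),
                     u3 = list(b = 0.16, k = 0.08, lag = 9))
    ),
    noise = noise, include_natural_abundance = include_natural_abundance,
    seed = seed)
}

#' Evaluate a scenario's true subunit fractions at a time
#'
#' @param scenario a [simulation_scenario()].
#' @param t time in hours (>= 0).
#' @return a [parameter_set()]: each labeled state at
#'   `b (1 - exp(-k max(0, t - lag)))`, unlabeled states at the closure
#'   remainder.
#' @export
trajectory <- function(scenario, t) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  fr <- numeric(0)
  for (su in scenario$space$subunits) {
    tr <- scenario$trajectories[[su$name]]
    block <- setNames(rep(0, length(su$parameter_names)), su$parameter_names)
    for (pn in names(tr)) {
      p <- tr[[pn]]
      lag <- if (is.null(p$lag)) 0 else p$lag
      block[pn] <- p$b * (1 - exp(-p$k * max(0, t - lag)))
    }
    block[1L] <- 1 - sum(block[-1L])
    if (block[1L] < -1e-9)
      stop(sprintf("subunit '%s': labeled fractions exceed 1 at t = %g",
                   su$name, t), call. = FALSE)
    block[1L] <- max(block[1L], 0)
    fr <- c(fr, block)
  }
  parameter_set(scenario$space, fr)
}

#' Simulate an isotopologue timecourse with known ground truth
#'
#' For each timepoint the forward model is evaluated at the scenario's true
#' fractions; optionally the profile is convolved with the natural 13C
#' abundance envelope (truncated to the model's mass axis and
#' renormalized); multiplicative Gaussian noise (sd = `noise`, truncated at
#' zero) is applied and the row renormalized. Deterministic for a fixed
#' scenario seed. The ground-truth sidecar contains everything needed to
#' regenerate the dataset bit-exactly.
#'
#' @param scenario a [simulation_scenario()].
#' @return a list of class `simulated_timecourse`: `data` (data.frame with
#'   `time` and `m0..mN` mole-fraction columns), `truth` (matrix of true
#'   subunit fractions, one row per timepoint) and `scenario`.
#' @examples
#' sim <- simulate_timecourse(default_scenario(seed = 7))
#' head(sim$data[, 1:6])
#' @export
simulate_timecourse <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sp <- scenario$space
  nmax <- max(mass_support(sp))
  settings <- correction_settings(metabolite_carbons(sp), p13 = scenario$p13)
  rows <- matrix(0, length(scenario$timepoints), nmax + 1L,
                 dimnames = list(NULL, paste0("m", 0:nmax)))
  truth <- NULL
  with_seed(scenario$seed, {
    for (i in seq_along(scenario$timepoints)) {
      pars <- trajectory(scenario, scenario$timepoints[i])
      truth <- rbind(truth, unclass(pars))
      prof <- as.numeric(predict_profile(sp, pars))
      if (scenario$include_natural_abundance) {
        prof <- convolve_natural_abundance(prof, settings)[seq_len(nmax + 1L)]
        prof <- prof / sum(prof)
      }
      if (scenario$noise > 0) {
        prof <- pmax(prof * (1 + rnorm(length(prof), sd = scenario$noise)), 0)
        prof <- prof / sum(prof)
      }
      rows[i, ] <- prof
    }
  })
  data <- data.frame(time = scenario$timepoints, rows, check.names = FALSE)
  structure(list(data = data, truth = truth, scenario = scenario),
            class = "simulated_timecourse")
}
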