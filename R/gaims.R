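#' GAIMS optimizer settings
#'
#' Hyperparameters of the hybrid simulated-annealing/genetic search. The
#' defaults reproduce the published configuration: a population of 20
#' candidates, 5% crossover rate, three variables mutated per step, a linear
#' annealing regime over 1e6 steps, and 50 independent repeats for
#' statistics. Tests and quick exploration can reduce `steps` and `repeats`.
#'
#' @param steps number of search steps per optimization (default 1e6).
#' @param population_size number of candidate parameter vectors (default 20).
#' @param crossover_rate probability that a step performs crossover between
#'   two candidates instead of mutation (default 0.05).
#' @param mutations_per_step number of free variables perturbed in a mutated
#'   candidate (default 3); capped at the number of free variables.
#' @param scale_init,scale_final initial and final per-variable perturbation
#'   magnitude of the linear annealing schedule (defaults 0.5 and 1e-4).
#' @param repeats independent optimizations for replicate statistics
#'   (default 50).
#' @param seed master integer seed; all randomness derives from it.
#' @return a list of class `gaims_settings`.
#' @export
gaims_settings <- function(steps = 1e6, population_size = 20,
                           crossover_rate = 0.05, mutations_per_step = 3,
                           scale_init = 0.5, scale_final = 1e-4,
                           repeats = 50, seed = 1L) {
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) stop("steps must be >= 1", call. = FALSE)
  if (population_size < 2L) stop("population_size must be >= 2", call. = FALSE)
  if (crossover_rate < 0 || crossover_rate > 1)
    stop("crossover_rate must be in [0, 1]", call. = FALSE)
  if (mutations_per_step < 1L)
    stop("mutations_per_step must be >= 1", call. = FALSE)
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  if (scale_init <= 0 || scale_final <= 0 || scale_final > scale_init)
    stop("need 0 < scale_final <= scale_init", call. = FALSE)
  structure(list(steps = steps, population_size = as.integer(population_size),
                 crossover_rate = crossover_rate,
                 mutations_per_step = as.integer(mutations_per_step),
                 scale_init = scale_init, scale_final = scale_final,
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "gaims_settings")
}

# align an observed profile onto the model mass axis 0..N_model, padding
# either side with zeros; strict mode errors on length mismatch
align_observed <- function(observed, space, align = FALSE) {
  obs <- as.numeric(observed)
  nmod <- max(mass_support(space)) + 1L
  if (length(obs) != nmod) {
    if (!align)
      stop(sprintf(
        "observed profile has %d mass channels but the model supports %d; set align = TRUE to zero-pad",
        length(obs), nmod), call. = FALSE)
    n <- max(length(obs), nmod)
    obs <- c(obs, numeric(n - length(obs)))
  }
  obs
}

#' GAIMS target function: sum of squared residuals
#'
#' `T = sum_n (I_n,obs - I_n,calc)^2` where the calculated profile is
#' [predict_profile()] at `params`. `T = 0` iff the model reproduces the
#' observation exactly.
#'
#' @param params a [parameter_set()] (or named fraction vector).
#' @param observed normalized observed profile over m0..mN.
#' @param space a [moiety_space()].
#' @param align zero-pad observed/calculated profiles to a common mass axis
#'   instead of erroring on length mismatch (default `FALSE`).
#' @return non-negative scalar T.
#' @export
gaims_objective <- function(params, observed, space, align = FALSE) {
  obs <- align_observed(observed, space, align)
  calc <- as.numeric(predict_profile(space, params))
  calc <- c(calc, numeric(length(obs) - length(calc)))
  sum((obs - calc)^2)
}

# flatten a moiety space for the C++ core
space_layout <- function(space) {
  list(n_states = vapply(space$subunits,
                         function(su) length(su$allowed_labels), integer(1)),
       labels = unlist(lapply(space$subunits, `[[`, "allowed_labels")),
       param_names = unlist(lapply(space$subunits, `[[`, "parameter_names")))
}

#' Run a single GAIMS optimization
#'
#' One hybrid simulated-annealing/genetic search: a population of candidate
#' fraction vectors is evolved by mutating randomly chosen free variables
#' with a perturbation magnitude that decays linearly over the run
#' (annealing), with occasional uniform crossover between candidates;
#' closure is enforced by projection onto each subunit's simplex and better
#' children greedily replace the worst population member. Deterministic for
#' a fixed seed.
#'
#' @param observed normalized observed isotopologue profile (m0..mN).
#' @param space a [moiety_space()].
#' @param settings a [gaims_settings()].
#' @param seed integer seed for this run (defaults to `settings$seed`).
#' @param align see [gaims_objective()].
#' @return a list with `params` (a [parameter_set()]), `objective` (the
#'   minimized T), `trace` (best-so-far T at regular intervals) and
#'   `evaluations`.
#' @export
gaims_fit_once <- function(observed, space, settings = gaims_settings(),
                           seed = settings$seed, align = FALSE) {
  stopifnot(inherits(space, "moiety_space"),
            inherits(settings, "gaims_settings"))
  obs <- align_observed(observed, space, align)
  if (abs(sum(obs) - 1) > 1e-6)
    warning("observed profile does not sum to 1; fitting as given",
            call. = FALSE)
  lay <- space_layout(space)
  res <- .gaims_core(lay$n_states, lay$labels, obs,
                     settings$steps, settings$population_size,
                     settings$crossover_rate, settings$mutations_per_step,
                     settings$scale_init, settings$scale_final,
                     as.double(seed))
  params <- parameter_set(space, setNames(res$params, lay$param_names),
                          tol = 1e-6)
  list(params = params, objective = res$objective, trace = res$trace,
       evaluations = res$evaluations, seed = as.integer(seed))
}

# deterministic per-repeat seed derivation from the master seed,
# kept within 32-bit integer range
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i * 16807) %% 2147483647)
}

#' Fit subunit labeling fractions with replicate statistics
#'
#' Repeats [gaims_fit_once()] with seeds derived deterministically from the
#' master seed and summarizes the replicate fits: the best solution, the
#' per-parameter mean and standard deviation across repeats, and residuals
#' of the best fit. Repeats whose best objectives differ by more than
#' `multimodal_tol` flag possible local minima.
#'
#' @inheritParams gaims_fit_once
#' @param multimodal_tol objective spread beyond which the fit is flagged
#'   multimodal (default 1e-4). `mean_params` averages only the repeats
#'   whose objective lies within this tolerance of the best repeat, so a
#'   repeat trapped in a different local basin does not drag the mean
#'   between modes; `sd_params` is computed over all repeats and therefore
#'   still exposes such basins.
#' @return a list of class `gaims_fit` with elements `best_params`,
#'   `best_objective`, `per_repeat_params` (matrix, repeats x states),
#'   `per_repeat_objective`, `mean_params`, `sd_params`, `residuals`,
#'   `multimodal`, `settings`.
#' @examples
#' sp <- udp_glcnac_space()
#' truth <- parameter_set(sp, c(g6 = 0.84, r5 = 0.93, a2 = 0.3,
#'                              u1 = 0.18, u2 = 0.46, u3 = 0.14))
#' obs <- predict_profile(sp, truth)
#' fit <- gaims_fit(obs, sp, gaims_settings(steps = 2e4, repeats = 3, seed = 7))
#' round(fit$best_params["g6"], 2)
#' @export
gaims_fit <- function(observed, space, settings = gaims_settings(),
                      align = FALSE, multimodal_tol = 1e-4) {
  runs <- lapply(seq_len(settings$repeats), function(i) {
    gaims_fit_once(observed, space, settings,
                   seed = derive_seed(settings$seed, i), align = align)
  })
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  pmat <- do.call(rbind, lapply(runs, function(r) unclass(r$params)))
  best_i <- which.min(objs)
  best <- runs[[best_i]]$params
  # average over the repeats that reached the best mode; repeats trapped in
  # a different local basin would otherwise pull the mean between modes,
  # which is meaningless as a parameter estimate. The sd over ALL repeats
  # (below) still exposes any multimodality.
  in_mode <- objs - objs[best_i] <= multimodal_tol
  mean_p <- parameter_set(space, colMeans(pmat[in_mode, , drop = FALSE]),
                          tol = 1e-6)
  sd_p <- if (nrow(pmat) > 1) apply(pmat, 2, sd) else
    setNames(rep(0, ncol(pmat)), colnames(pmat))
  obs <- align_observed(observed, space, align)
  calc <- as.numeric(predict_profile(space, best))
  calc <- c(calc, numeric(length(obs) - length(calc)))
  structure(list(
    best_params = best, best_objective = objs[best_i],
    per_repeat_params = pmat, per_repeat_objective = objs,
    mean_params = mean_p, sd_params = sd_p,
    residuals = setNames(obs - calc, paste0("m", seq_along(obs) - 1L)),
    multimodal = diff(range(objs)) > multimodal_tol,
    settings = settings), class = "gaims_fit")
}

#' @export
print.gaims_fit <- function(x, ...) {
  cat(sprintf("GAIMS fit: %d repeats, best T = %.3g%s\n",
              length(x$per_repeat_objective), x$best_objective,
              if (x$multimodal) " (multimodal)" else ""))
  tab <- rbind(best = unclass(x$best_params),
               mean = unclass(x$mean_params), sd = x$sd_params)
  print(round(tab, 4))
  invisible(x)
}
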