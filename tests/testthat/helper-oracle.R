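# Independent brute-force oracle for the forward model: sum the fraction
# products over every enumerated joint isotopomer state, parsing the
# product expressions rather than convolving.
oracle_profile <- function(space, params) {
  iso <- enumerate_isotopomers(space)
  out <- numeric(max(iso$mass_shift) + 1L)
  for (r in seq_len(nrow(iso))) {
    pn <- strsplit(iso$expression[r], "*", fixed = TRUE)[[1L]]
    out[iso$mass_shift[r] + 1L] <- out[iso$mass_shift[r] + 1L] +
      prod(unclass(params)[pn])
  }
  out
}

# random small state space: <= 5 subunits, <= 4 states each
random_space <- function() {
  ns <- sample(1:5, 1)
  moiety_space(lapply(seq_len(ns), function(i) {
    cc <- sample(1:6, 1)
    labs <- sort(sample(0:cc, sample(1:min(4, cc + 1L), 1)))
    moiety_subunit(paste0("s", i), cc, labs, paste0("s", i, "_", labs))
  }), name = "random")
}

# uniform draw on each subunit's simplex
random_params <- function(space) {
  fr <- unlist(lapply(space$subunits, function(su) {
    x <- rexp(length(su$allowed_labels))
    setNames(x / sum(x), su$parameter_names)
  }))
  parameter_set(space, fr)
}

# the published 48 h deconvolution of UDP-GlcNAc (u0 by closure)
params_48h <- function(space = udp_glcnac_space()) {
  parameter_set(space, c(g6 = 0.84, r5 = 0.93, a2 = 0.3,
                         u1 = 0.18, u2 = 0.46, u3 = 0.14))
}

expt_times <- c(0, 3, 6, 11, 24, 34, 48)

# reduced-cost optimizer settings for tests (default remains 1e6 steps)
test_settings <- function(steps = 2e4, repeats = 3, seed = 1L, ...) {
  gaims_settings(steps = steps, repeats = repeats, seed = seed, ...)
}
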