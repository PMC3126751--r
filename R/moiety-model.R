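#' Define a biochemical subunit and its allowed labeling states
#'
#' A subunit (moiety) is a building block of a modular metabolite, e.g. the
#' glucose, ribose, acetyl or uracil unit of UDP-GlcNAc. Each subunit carries
#' a set of allowed 13C label counts (its isotopomer states) and one mole
#' fraction parameter per state.
#'
#' @param name subunit identifier, e.g. `"glucose"`.
#' @param carbon_count number of carbon atoms in the subunit (>= 1).
#' @param allowed_labels integer vector of allowed 13C counts; each must lie
#'   in `[0, carbon_count]`. Sorted and deduplicated internally.
#' @param parameter_names one identifier per allowed label state. Defaults to
#'   the first letter of `name` followed by the label count (`g0`, `g6`, ...).
#' @return an object of class `moiety_subunit`.
#' @examples
#' moiety_subunit("glucose", 6, c(0, 6))
#' @export
moiety_subunit <- function(name, carbon_count, allowed_labels,
                           parameter_names = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  carbon_count <- as.integer(carbon_count)
  if (is.na(carbon_count) || carbon_count < 1L)
    stop("carbon_count must be an integer >= 1", call. = FALSE)
  allowed_labels <- sort(unique(as.integer(allowed_labels)))
  if (length(allowed_labels) == 0L)
    stop("allowed_labels must be non-empty", call. = FALSE)
  if (any(allowed_labels < 0L) || any(allowed_labels > carbon_count))
    stop(sprintf("allowed_labels of subunit '%s' must lie in [0, %d]",
                 name, carbon_count), call. = FALSE)
  if (is.null(parameter_names))
    parameter_names <- paste0(substr(tolower(name), 1L, 1L), allowed_labels)
  parameter_names <- as.character(parameter_names)
  if (length(parameter_names) != length(allowed_labels))
    stop(sprintf("subunit '%s': need one parameter name per allowed label",
                 name), call. = FALSE)
  if (anyDuplicated(parameter_names))
    stop(sprintf("subunit '%s': parameter names must be distinct", name),
         call. = FALSE)
  structure(
    list(name = name, carbon_count = carbon_count,
         allowed_labels = allowed_labels, parameter_names = parameter_names),
    class = "moiety_subunit"
  )
}

#' Define a moiety state space for a modular metabolite
#'
#' The state space is the ordered list of subunits, whose joint labeling
#' states generate the metabolite's isotopologue distribution. For
#' UDP-GlcNAc see [udp_glcnac_space()].
#'
#' @param subunits list of [moiety_subunit()] objects (at least one).
#' @param name metabolite name.
#' @return an object of class `moiety_space`.
#' @examples
#' sp <- moiety_space(list(
#'   moiety_subunit("glucose", 6, c(0, 6)),
#'   moiety_subunit("ribose", 5, c(0, 5))
#' ), name = "toy")
#' metabolite_carbons(sp)
#' @export
moiety_space <- function(subunits, name = "metabolite") {
  if (!is.list(subunits) || length(subunits) == 0L)
    stop("a moiety space needs at least one subunit", call. = FALSE)
  ok <- vapply(subunits, inherits, logical(1), "moiety_subunit")
  if (!all(ok))
    stop("all elements of 'subunits' must be moiety_subunit objects",
         call. = FALSE)
  nm <- vapply(subunits, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("subunit names must be distinct", call. = FALSE)
  pn <- unlist(lapply(subunits, `[[`, "parameter_names"))
  if (anyDuplicated(pn))
    stop("parameter names must be distinct across subunits", call. = FALSE)
  structure(list(name = name, subunits = subunits), class = "moiety_space")
}

#' @export
print.moiety_space <- function(x, ...) {
  cat(sprintf("Moiety state space '%s': %d subunits, %d carbons\n",
              x$name, length(x$subunits), metabolite_carbons(x)))
  for (su in x$subunits) {
    cat(sprintf("  %-10s %2d C  labels {%s}  params {%s}\n", su$name,
                su$carbon_count, paste(su$allowed_labels, collapse = ","),
                paste(su$parameter_names, collapse = ",")))
  }
  cat(sprintf("  %d isotopomers, %d isotopologue masses, %d free parameters\n",
              nrow(enumerate_isotopomers(x)), length(mass_support(x)),
              free_parameter_count(x)))
  invisible(x)
}

#' Total carbon count of a moiety space
#'
#' @param space a [moiety_space()].
#' @return integer sum of subunit carbon counts (17 for UDP-GlcNAc).
#' @export
metabolite_carbons <- function(space) {
  stopifnot(inherits(space, "moiety_space"))
  sum(vapply(space$subunits, `[[`, integer(1), "carbon_count"))
}

#' The default UDP-GlcNAc moiety state space
#'
#' UDP-GlcNAc (17 carbons) is modeled as four subunits labeled from
#' [U-13C]-glucose: glucose (6 C, all-or-none: labels 0/6), ribose
#' (5 C, 0/5), acetyl (2 C, 0/2) and the uracil ring (4 C, labels 0-3;
#' one ring carbon derives from bicarbonate and stays unlabeled).
#' This yields 32 joint isotopomers, masses m0..m16 and 6 free parameters
#' (g0, r0, a0, u0, u1, u2; the complements are implied by closure).
#'
#' @return a `moiety_space` object.
#' @examples
#' udp_glcnac_space()
#' @export
udp_glcnac_space <- function() {
  moiety_space(list(
    moiety_subunit("glucose", 6L, c(0L, 6L), c("g0", "g6")),
    moiety_subunit("ribose",  5L, c(0L, 5L), c("r0", "r5")),
    moiety_subunit("acetyl",  2L, c(0L, 2L), c("a0", "a2")),
    moiety_subunit("uracil",  4L, 0:3,       c("u0", "u1", "u2", "u3"))
  ), name = "UDP-GlcNAc")
}

#' Enumerate all joint isotopomer states of a moiety space
#'
#' Takes the Cartesian product of the subunits' allowed label states. Each
#' joint state carries its total mass shift (sum of labels) and the product
#' expression of parameter names whose value is its mole fraction.
#'
#' @param space a [moiety_space()].
#' @return a data.frame with one column of labels per subunit, plus
#'   `mass_shift` (total 13C count) and `expression` (e.g. `"g6*r5*a0*u2"`).
#'   The default UDP-GlcNAc space yields 32 rows.
#' @examples
#' nrow(enumerate_isotopomers(udp_glcnac_space()))  # 32
#' @export
enumerate_isotopomers <- function(space) {
  stopifnot(inherits(space, "moiety_space"))
  labs <- lapply(space$subunits, `[[`, "allowed_labels")
  names(labs) <- vapply(space$subunits, `[[`, character(1), "name")
  grid <- expand.grid(labs, KEEP.OUT.ATTRS = FALSE)
  pn <- mapply(function(su, lab) su$parameter_names[match(lab, su$allowed_labels)],
               space$subunits, grid, SIMPLIFY = FALSE)
  grid$mass_shift <- as.integer(rowSums(grid))
  grid$expression <- do.call(paste, c(pn, sep = "*"))
  grid
}

#' Achievable isotopologue mass shifts of a moiety space
#'
#' @param space a [moiety_space()].
#' @return sorted integer vector of distinct achievable total 13C counts.
#'   For the default UDP-GlcNAc space this is `0:16` (17 masses; m17 is
#'   unreachable because the uracil ring carries at most 3 labeled carbons).
#' @examples
#' length(mass_support(udp_glcnac_space()))  # 17
#' @export
mass_support <- function(space) {
  sort(unique(enumerate_isotopomers(space)$mass_shift))
}

#' Number of free labeling parameters of a moiety space
#'
#' Each subunit's state fractions sum to one (closure), so a subunit with
#' `s` allowed states contributes `s - 1` free parameters.
#'
#' @param space a [moiety_space()].
#' @return integer; 6 for the default UDP-GlcNAc space.
#' @export
free_parameter_count <- function(space) {
  stopifnot(inherits(space, "moiety_space"))
  sum(vapply(space$subunits, function(su) length(su$allowed_labels) - 1L,
             integer(1)))
}

#' Construct and validate a subunit labeling parameter set
#'
#' A parameter set maps every state parameter name to a mole fraction in
#' `[0, 1]`. Within each subunit the fractions must satisfy closure (sum to
#' one). Sums within `tol` of one are silently renormalized; larger
#' violations are an error. Parameters omitted from `fractions` are filled
#' by closure when exactly one state per subunit is missing.
#'
#' @param space a [moiety_space()].
#' @param fractions named numeric vector (or list) of mole fractions.
#' @param tol closure tolerance (default `1e-9`).
#' @return named numeric vector of class `parameter_set`, ordered as the
#'   concatenated subunit parameter names, each subunit block summing to 1.
#' @examples
#' parameter_set(udp_glcnac_space(),
#'               c(g6 = 0.84, r5 = 0.93, a2 = 0.3, u1 = 0.18, u2 = 0.46, u3 = 0.14))
#' @export
parameter_set <- function(space, fractions, tol = 1e-9) {
  stopifnot(inherits(space, "moiety_space"))
  fractions <- unlist(fractions)
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("fractions must be named by state parameter", call. = FALSE)
  all_names <- unlist(lapply(space$subunits, `[[`, "parameter_names"))
  unknown <- setdiff(names(fractions), all_names)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(fractions)) || any(fractions < -tol) ||
      any(fractions > 1 + tol))
    stop("fractions must be finite and in [0, 1]", call. = FALSE)
  out <- numeric(0)
  for (su in space$subunits) {
    block <- setNames(rep(NA_real_, length(su$parameter_names)),
                      su$parameter_names)
    got <- intersect(names(fractions), su$parameter_names)
    block[got] <- fractions[got]
    miss <- is.na(block)
    if (sum(miss) == 1L) {
      # a single omitted state is implied by closure
      block[miss] <- 1 - sum(block[!miss])
      if (block[which(miss)] < -tol)
        stop(sprintf("subunit '%s': specified fractions exceed 1", su$name),
             call. = FALSE)
      block[miss] <- max(block[which(miss)], 0)
    } else if (any(miss)) {
      # several omitted states default to zero; closure is then checked
      block[miss] <- 0
    }
    s <- sum(block)
    if (abs(s - 1) > tol)
      stop(sprintf("subunit '%s': fractions sum to %.12g, not 1 (tol %g)",
                   su$name, s, tol), call. = FALSE)
    out <- c(out, pmin(pmax(block / s, 0), 1))
  }
  structure(out, class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Subunit labeling fractions:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

# per-subunit mass distribution: numeric vector over 0..carbon_count
subunit_distribution <- function(su, params) {
  d <- numeric(su$carbon_count + 1L)
  d[su$allowed_labels + 1L] <- params[su$parameter_names]
  d
}

#' Construct an isotopologue profile object
#'
#' @param fractions non-negative numeric vector of mole fractions for mass
#'   shifts `0..N` (in order).
#' @param normalized if `TRUE` (default), rescale to sum to one.
#' @return numeric vector of class `isotopologue_profile`, named `m0..mN`.
#' @export
isotopologue_profile <- function(fractions, normalized = TRUE) {
  fractions <- as.numeric(fractions)
  if (any(!is.finite(fractions)) || any(fractions < 0))
    stop("profile fractions must be finite and non-negative", call. = FALSE)
  if (normalized) {
    s <- sum(fractions)
    if (s <= 0) stop("profile has no signal", call. = FALSE)
    fractions <- fractions / s
  }
  structure(setNames(fractions, paste0("m", seq_along(fractions) - 1L)),
            class = "isotopologue_profile")
}

#' Predict the isotopologue distribution from subunit labeling fractions
#'
#' The forward model: the metabolite's mass-shift distribution is the
#' convolution of its subunits' label distributions, i.e. the intensity at
#' mass shift `n` is the sum over all joint isotopomer states totaling `n`
#' of the product of the participating state fractions.
#'
#' @param space a [moiety_space()].
#' @param params a [parameter_set()] for `space` (or a named vector coerced
#'   through `parameter_set()`).
#' @return an `isotopologue_profile` over mass shifts `0..N`, where `N` is
#'   the maximum achievable total label; sums to 1. Unreachable masses below
#'   `N` are reported as exact zeros.
#' @examples
#' sp <- udp_glcnac_space()
#' p <- parameter_set(sp, c(g6 = 0.84, r5 = 0.93, a2 = 0.3,
#'                          u1 = 0.18, u2 = 0.46, u3 = 0.14))
#' predict_profile(sp, p)
#' @export
predict_profile <- function(space, params) {
  stopifnot(inherits(space, "moiety_space"))
  if (!inherits(params, "parameter_set"))
    params <- parameter_set(space, params)
  nmax <- max(mass_support(space))
  out <- 1
  for (su in space$subunits)
    out <- convolve_vectors(out, subunit_distribution(su, params))
  out <- out[seq_len(nmax + 1L)]  # trailing entries beyond support are 0
  isotopologue_profile(out, normalized = FALSE)
}

# plain linear convolution (small vectors; outer-product accumulation)
convolve_vectors <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Mean mass shift of an isotopologue profile
#'
#' @param profile an `isotopologue_profile` (or numeric vector over m0..mN).
#' @return `sum(n * I_n) / sum(I_n)`, the average number of 13C atoms.
#' @export
mean_mass_shift <- function(profile) {
  p <- as.numeric(profile)
  sum((seq_along(p) - 1L) * p) / sum(p)
}
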