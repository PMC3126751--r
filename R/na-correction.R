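#' Natural-abundance correction settings
#'
#' @param carbon_count total number of carbon atoms in the metabolite
#'   (17 for UDP-GlcNAc).
#' @param p13 natural 13C abundance as a fraction (default 0.011).
#' @param clamp_negative clamp small negative post-correction intensities to
#'   zero (default `TRUE`); the clamped magnitude is reported in the result.
#' @return a list of class `correction_settings`.
#' @export
correction_settings <- function(carbon_count, p13 = 0.011,
                                clamp_negative = TRUE) {
  carbon_count <- as.integer(carbon_count)
  if (is.na(carbon_count) || carbon_count < 1L)
    stop("carbon_count must be a positive integer", call. = FALSE)
  if (!is.finite(p13) || p13 < 0 || p13 >= 0.5)
    stop("p13 must lie in [0, 0.5)", call. = FALSE)
  structure(list(carbon_count = carbon_count, p13 = p13,
                 clamp_negative = isTRUE(clamp_negative)),
            class = "correction_settings")
}

#' Normalize raw isotopologue intensities to mole fractions
#'
#' Divides each intensity by the summed intensity of all isotopologues so
#' the result is the mole fraction of each species.
#'
#' @param raw non-negative numeric vector of intensities for m0..mN.
#' @return an [isotopologue_profile()] summing to one.
#' @examples
#' normalize_profile(c(1, 2, 3, 4))
#' @export
normalize_profile <- function(raw) {
  raw <- as.numeric(raw)
  if (any(!is.finite(raw)) || any(raw < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  if (sum(raw) <= 0)
    stop("cannot normalize: total intensity is zero", call. = FALSE)
  isotopologue_profile(raw, normalized = TRUE)
}

# binomial natural-abundance envelope of a species with `enriched` 13C atoms:
# weights over extra masses j = 0..(carbon_count - enriched)
na_envelope <- function(enriched, settings) {
  free_c <- settings$carbon_count - enriched
  stats::dbinom(0:free_c, size = free_c, prob = settings$p13)
}

#' Convolve an enrichment distribution with the natural-abundance envelope
#'
#' Forward transform: each species with `e` tracer-derived 13C atoms spreads
#' over masses `e + j` with binomial weights `C(C-e, j) p13^j (1-p13)^(C-e-j)`
#' over its `C - e` unenriched carbon positions. This is the inverse of
#' [strip_natural_abundance()].
#'
#' @param x numeric vector of enrichment-only intensities for m0..mN
#'   (N <= carbon_count).
#' @param settings a [correction_settings()].
#' @return numeric vector over m0..m`carbon_count` including natural
#'   abundance; total signal is preserved.
#' @export
convolve_natural_abundance <- function(x, settings) {
  stopifnot(inherits(settings, "correction_settings"))
  x <- as.numeric(x)
  C <- settings$carbon_count
  if (length(x) - 1L > C)
    stop("input has more mass shifts than carbon_count allows", call. = FALSE)
  out <- numeric(C + 1L)
  for (e in seq_along(x) - 1L) {
    if (x[e + 1L] == 0) next
    w <- na_envelope(e, settings)
    idx <- (e + 1L):(e + length(w))
    out[idx] <- out[idx] + x[e + 1L] * w
  }
  setNames(out, paste0("m", 0:C))
}

#' Strip natural-abundance 13C contributions from isotopologue intensities
#'
#' Sequentially from the lowest mass upward, each corrected species'
#' natural-abundance envelope (binomial over its unenriched carbon
#' positions) is subtracted from the higher masses, then the species itself
#' is rescaled by its monoisotopic envelope weight. The corrected vector
#' re-convolved with the envelopes reproduces the input to numerical
#' tolerance (exactly, when clamping never triggers). Only 13C is corrected:
#' at FT-ICR-MS resolution 2H/15N/18O isotopologues are resolved away.
#'
#' @param raw non-negative numeric intensity vector for m0..mN.
#' @param settings a [correction_settings()]; `p13 = 0` is the identity.
#' @return numeric vector of corrected intensities, same length as `raw`,
#'   with attribute `clamped` giving the total magnitude of negative values
#'   clamped to zero (0 when clamping is off or never needed).
#' @examples
#' s <- correction_settings(carbon_count = 17, p13 = 0.011)
#' env <- convolve_natural_abundance(c(1), s)   # pure unlabeled C17 envelope
#' strip_natural_abundance(env[1:17], s)        # all mass back at m0
#' @export
strip_natural_abundance <- function(raw, settings) {
  stopifnot(inherits(settings, "correction_settings"))
  raw <- as.numeric(raw)
  if (length(raw) < 1L) stop("empty intensity vector", call. = FALSE)
  if (any(!is.finite(raw))) stop("intensities must be finite", call. = FALSE)
  C <- settings$carbon_count
  if (length(raw) - 1L > C)
    stop("more mass shifts than carbons", call. = FALSE)
  corrected <- raw
  clamped <- 0
  n <- length(raw)
  for (e in seq_len(n) - 1L) {
    w <- na_envelope(e, settings)
    # solve the triangular system: raw[e] = sum_{e'<=e} corr[e'] w[e', e-e']
    val <- corrected[e + 1L] / w[1L]
    if (val < 0 && settings$clamp_negative) {
      clamped <- clamped + abs(val)
      val <- 0
    }
    corrected[e + 1L] <- val
    if (e + 2L <= n && val != 0) {
      idx <- (e + 2L):min(n, e + length(w))
      corrected[idx] <- corrected[idx] - val * w[seq_along(idx) + 1L]
    }
  }
  if (clamped > 1e-9 * max(sum(abs(raw)), 1e-300))  # ignore float dust
    warning(sprintf("natural-abundance stripping clamped %.3g total negative intensity to zero",
                    clamped), call. = FALSE)
  structure(setNames(corrected, paste0("m", seq_len(n) - 1L)),
            clamped = clamped)
}
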