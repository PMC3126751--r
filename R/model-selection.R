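#' Generate variant labeling models from a grammar of alternatives
#'
#' Variant moiety models encode alternative biosynthetic hypotheses, e.g.
#' partial 13C labeling of the acetyl unit (`{0,1,2}` instead of all-or-none
#' `{0,2}`) or scrambling into additional ribose states. The grammar lists,
#' per subunit, the alternative allowed-label sets; variants are all
#' combinations across subunits (deduplicated, base model included).
#'
#' @param base a [moiety_space()].
#' @param grammar named list: for each subunit name, a list of integer
#'   vectors of alternative allowed-label sets. Subunits absent from the
#'   grammar keep their base label set. The base set is always included.
#' @return a list of `model_variant` objects, each with elements `space`,
#'   `description` and `k` (free parameter count). The base model is first.
#' @examples
#' vars <- generate_variants(udp_glcnac_space(),
#'                           list(acetyl = list(c(0, 1, 2))))
#' length(vars)  # 2: base and full-acetyl
#' @export
generate_variants <- function(base, grammar = default_variant_grammar()) {
  stopifnot(inherits(base, "moiety_space"))
  sub_names <- vapply(base$subunits, `[[`, character(1), "name")
  unknown <- setdiff(names(grammar), sub_names)
  if (length(unknown))
    stop("grammar names unknown subunits: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  alts <- lapply(seq_along(base$subunits), function(i) {
    su <- base$subunits[[i]]
    sets <- c(list(su$allowed_labels),
              if (su$name %in% names(grammar)) grammar[[su$name]] else list())
    sets <- lapply(sets, function(s) sort(unique(as.integer(s))))
    if (any(vapply(sets, length, integer(1)) == 0L))
      stop(sprintf("grammar produced an empty label set for '%s'", su$name),
           call. = FALSE)
    unique(sets)
  })
  combos <- expand.grid(lapply(alts, seq_along), KEEP.OUT.ATTRS = FALSE)
  # put the all-base combination first
  ord <- order(rowSums(combos != 1L), seq_len(nrow(combos)))
  combos <- combos[ord, , drop = FALSE]
  lapply(seq_len(nrow(combos)), function(r) {
    subs <- lapply(seq_along(base$subunits), function(i) {
      su <- base$subunits[[i]]
      labs <- alts[[i]][[combos[r, i]]]
      moiety_subunit(su$name, su$carbon_count, labs,
                     paste0(substr(tolower(su$name), 1L, 1L), labs))
    })
    desc <- paste(vapply(subs, function(su)
      sprintf("%s{%s}", su$name, paste(su$allowed_labels, collapse = ",")),
      character(1)), collapse = " ")
    sp <- moiety_space(subs, name = paste0(base$name, " variant ", r))
    structure(list(space = sp, description = desc,
                   k = free_parameter_count(sp)), class = "model_variant")
  })
}

#' Default variant grammar for the UDP-GlcNAc model
#'
#' Alternatives reflecting biosynthetic hypotheses beyond the base
#' all-or-none model: partial glucose labeling via scrambling, partially
#' labeled riboses from the non-oxidative pentose phosphate pathway,
#' singly labeled acetyl (13C1-acetate), and uracil states allowing a
#' bicarbonate-derived fourth ring label or missing single labels. Combined
#' across subunits this produces 54 variant models.
#'
#' @return named list of per-subunit alternative label sets.
#' @export
default_variant_grammar <- function() {
  list(
    glucose = list(c(0, 3, 6)),
    ribose  = list(c(0, 4, 5), c(0, 1, 2, 3, 4, 5)),
    acetyl  = list(c(0, 1, 2), c(0)),
    uracil  = list(c(0, 1, 2, 3, 4), c(0, 2, 3))
  )
}

#' Least-squares Akaike information criterion
#'
#' For Gaussian residuals, `AIC = n ln(RSS/n) + 2k`. Because each timepoint
#' supplies few observations (17 masses for UDP-GlcNAc), the small-sample
#' correction `AICc = AIC + 2k(k+1)/(n-k-1)` is applied by default.
#'
#' @param rss residual sum of squares (>= 0).
#' @param n_obs number of observations.
#' @param k number of free parameters.
#' @param corrected apply the AICc small-sample correction (default `TRUE`).
#' @return the criterion value; `-Inf` with a warning when `rss == 0`.
#' @export
aic_ls <- function(rss, n_obs, k, corrected = TRUE) {
  if (rss < 0) stop("rss must be non-negative", call. = FALSE)
  if (corrected && n_obs <= k + 1)
    stop("AICc needs n_obs > k + 1", call. = FALSE)
  if (rss == 0) {
    warning("rss is exactly 0 (perfect fit); AIC is -Inf", call. = FALSE)
    return(-Inf)
  }
  a <- n_obs * log(rss / n_obs) + 2 * k
  if (corrected) a <- a + 2 * k * (k + 1) / (n_obs - k - 1)
  a
}

#' Select among variant moiety models by AICc
#'
#' Every variant is fitted to every timepoint's observed profile with
#' [gaims_fit()]; the criterion per timepoint is evaluated at the
#' across-repeat mean parameter vector (or at the best-fit vector) and
#' summed over timepoints. Variants are ranked by the summed criterion.
#' Fit failures are caught per variant and ranked last with their reason.
#'
#' @param variants list from [generate_variants()] (or of `moiety_space`
#'   objects).
#' @param observed list (or matrix, rows = timepoints) of normalized
#'   observed profiles sharing one mass axis.
#' @param settings a [gaims_settings()]; seeds are derived per variant and
#'   timepoint so the selection is deterministic.
#' @param corrected use AICc (default) or plain AIC.
#' @param at evaluate the criterion at the `"mean"` (default) or `"best"`
#'   parameter vector.
#' @param rss_floor lower bound on the per-timepoint residual sum of squares
#'   (default 1e-12). A timepoint fitted exactly (common at t = 0, where the
#'   corrected profile is a single peak) would otherwise contribute -Inf for
#'   every variant and void the comparison; at the floor the parameter-count
#'   penalty decides, as it should for indistinguishable fits.
#' @return a data.frame of class `selection_report`, sorted by AIC, with
#'   columns `variant`, `description`, `k`, `rss`, `aic`, `delta_aic`,
#'   `rank`, `error`; the fitted models are in `attr(, "fits")`.
#' @export
select_model <- function(variants, observed, settings = gaims_settings(),
                         corrected = TRUE, at = c("mean", "best"),
                         rss_floor = 1e-12) {
  at <- match.arg(at)
  if (inherits(variants, "moiety_space")) variants <- list(variants)
  variants <- lapply(variants, function(v) {
    if (inherits(v, "model_variant")) v
    else structure(list(space = v, description = v$name,
                        k = free_parameter_count(v)), class = "model_variant")
  })
  if (is.matrix(observed) || is.data.frame(observed))
    observed <- lapply(seq_len(nrow(observed)),
                       function(i) as.numeric(observed[i, ]))
  n_obs_total <- sum(lengths(observed))
  rows <- vector("list", length(variants))
  fits <- vector("list", length(variants))
  for (v in seq_along(variants)) {
    var <- variants[[v]]
    res <- tryCatch({
      aic_sum <- 0
      rss_sum <- 0
      vfits <- vector("list", length(observed))
      for (ti in seq_along(observed)) {
        st <- settings
        st$seed <- derive_seed(settings$seed, v * 1000L + ti)
        fit <- gaims_fit(observed[[ti]], var$space, st, align = TRUE)
        pars <- if (at == "mean") fit$mean_params else fit$best_params
        rss <- gaims_objective(pars, observed[[ti]], var$space, align = TRUE)
        aic_sum <- aic_sum + aic_ls(max(rss, rss_floor),
                                    length(observed[[ti]]), var$k,
                                    corrected = corrected)
        rss_sum <- rss_sum + rss
        vfits[[ti]] <- fit
      }
      fits[[v]] <- vfits
      list(rss = rss_sum, aic = aic_sum, error = NA_character_)
    }, error = function(e) list(rss = NA_real_, aic = Inf,
                                error = conditionMessage(e)))
    rows[[v]] <- data.frame(variant = v, description = var$description,
                            k = var$k, rss = res$rss, aic = res$aic,
                            error = res$error, stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, rows)
  rep <- rep[order(rep$aic), , drop = FALSE]
  finite_min <- min(rep$aic[is.finite(rep$aic)], na.rm = TRUE)
  rep$delta_aic <- rep$aic - finite_min
  rep$rank <- seq_len(nrow(rep))
  rownames(rep) <- NULL
  structure(rep[, c("rank", "variant", "description", "k", "rss", "aic",
                    "delta_aic", "error")],
            fits = fits, n_obs = n_obs_total,
            class = c("selection_report", "data.frame"))
}
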