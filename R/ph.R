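#' Protonated fraction of a single site
#'
#' Henderson-Hasselbalch fraction of the protonated form at a given pH.
#' For a basic site (BH+ <-> B) this is the ammonium fraction; for an
#' acidic site (HA <-> A-) the neutral-acid fraction. Both follow
#' \deqn{f_{prot}(pH) = \frac{1}{1 + 10^{pH - pK_a}}.}
#'
#' @param pKa Site pKa (dimensionless). Vectorized with `pH`.
#' @param pH pH value(s).
#' @return Fraction in \[0, 1\] of the protonated microform.
#' @examples
#' fraction_protonated(9.31, 7.31)  # dopamine ammonium, ~0.990
#' fraction_protonated(4.96, 6.96)  # ~0.0099
#' @export
fraction_protonated <- function(pKa, pH) {
  if (any(!is.finite(pKa)) || any(!is.finite(pH))) {
    abort("pKa and pH must be finite")
  }
  1 / (1 + 10^(pH - pKa))
}

#' Microspecies fractions over a pH grid
#'
#' Enumerates all 2^k protonation microstates of k sites under the
#' independent-site approximation: each microstate's fraction is the
#' product of its per-site Henderson-Hasselbalch fractions, so fractions
#' sum to 1 at every pH. Site coupling (microstate-specific pKa shifts)
#' is not modeled; pKa values are taken as given.
#'
#' @param sites Data frame with columns `site_id`, `pKa` and `site_class`
#'   (`"acid"` or `"base"`). At most 12 sites (combinatorial guard).
#' @param pH_grid Numeric vector of pH values (default 2 to 13 by 0.1,
#'   the range over which sensor responses were measured).
#' @return A tibble of class `nanosar_microspecies`, long format:
#'   `pH`, `microspecies` (label listing the protonated sites), `fraction`.
#' @examples
#' sites <- data.frame(site_id = "NH3", pKa = 9.31, site_class = "base")
#' prof <- microspecies_profile(sites)
#' @export
microspecies_profile <- function(sites, pH_grid = seq(2, 13, by = 0.1)) {
  check_columns(sites, c("site_id", "pKa", "site_class"), "sites")
  k <- nrow(sites)
  if (k < 1) abort("need at least one protonation site")
  if (k > 12) abort("more than 12 sites: microstate enumeration refused")
  if (length(pH_grid) < 1) abort("pH grid is empty")
  if (!all(sites$site_class %in% c("acid", "base"))) {
    abort("site_class must be 'acid' or 'base'")
  }

  # per-site protonated fraction: rows = pH, cols = sites
  fprot <- vapply(seq_len(k),
                  function(i) fraction_protonated(sites$pKa[i], pH_grid),
                  numeric(length(pH_grid)))
  fprot <- matrix(fprot, nrow = length(pH_grid))

  states <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k)))
  colnames(states) <- sites$site_id
  label_of <- function(st) {
    tags <- ifelse(st, paste0(sites$site_id, "(H)"),
                   paste0(sites$site_id, "(-)"))
    paste(tags, collapse = "/")
  }

  out <- purrr::map_dfr(seq_len(nrow(states)), function(s) {
    st <- states[s, ]
    frac <- rep(1, length(pH_grid))
    for (i in seq_len(k)) {
      frac <- frac * (if (st[i]) fprot[, i] else 1 - fprot[, i])
    }
    tibble(pH = pH_grid, microspecies = label_of(st), fraction = frac)
  })
  class(out) <- c("nanosar_microspecies", class(out))
  out
}

#' Correlate a pH-response profile with a microspecies transition
#'
#' Quantifies the visual juxtaposition of a sensor's \eqn{\Delta F}(pH)
#' profile against a protonation microspecies curve: the microspecies
#' fraction is linearly interpolated onto the measured pH values and the
#' Pearson correlation between response and fraction is returned. A
#' response that tracks an ammonium-to-amine transition gives |r| near 1.
#'
#' @param response_vs_pH Data frame with columns `pH` and `dF` (or set
#'   `response_col`).
#' @param profile A [microspecies_profile()] result.
#' @param microspecies Label of the microspecies to correlate against.
#' @param response_col Response column (default `"dF"`, raw fluorescence
#'   change; pass `"dFF"` to use relative change instead).
#' @return A `nanosar_cor` object (see [pearson_cor()]).
#' @export
overlay_transition <- function(response_vs_pH, profile, microspecies,
                               response_col = "dF") {
  check_columns(response_vs_pH, c("pH", response_col), "response_vs_pH")
  check_columns(profile, c("pH", "microspecies", "fraction"), "profile")
  curve <- profile[profile$microspecies == microspecies, ]
  if (nrow(curve) == 0) {
    abort(sprintf("microspecies '%s' not found in profile; available: %s",
                  microspecies,
                  paste(unique(profile$microspecies), collapse = ", ")))
  }
  in_range <- response_vs_pH$pH >= min(curve$pH) &
    response_vs_pH$pH <= max(curve$pH)
  obs <- response_vs_pH[in_range, ]
  if (nrow(obs) < 3) {
    abort(sprintf("only %d pH points overlap the profile grid (need >= 3)",
                  nrow(obs)))
  }
  frac <- approx(curve$pH, curve$fraction, xout = obs$pH)$y
  pearson_cor(obs[[response_col]], frac)
}
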