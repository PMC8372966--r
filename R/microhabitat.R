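#' The six microhabitat classification schemes
#'
#' Schemes differ along three axes: whether semi-aquatic (SW) is kept as
#' its own category (`7-` schemes) or remapped (`6-` schemes), whether
#' the secondary microhabitat can override a terrestrial primary
#' (lenient `-L` vs majority-rule `-M`), and whether an alternative
#' arboreality source forces species flagged there into the arboreal
#' category (`-Mc-` schemes).
#'
#' @return Character vector of the six scheme identifiers.
#' @export
microhabitat_schemes <- function() {
  c("6-M", "6-L", "7-M", "7-L", "6-McM", "6-McL")
}

#' Microhabitat category codes
#' @return The seven valid input codes: arboreal (A), cave (C),
#'   fossorial (F), saxicolous (S), terrestrial (T), aquatic (W),
#'   semi-aquatic (SW).
#' @export
microhabitat_codes <- function() c("A", "C", "F", "S", "T", "W", "SW")

#' Classify a species' microhabitat under a scheme
#'
#' Pure, vectorized mapping from primary/secondary codes (plus the
#' alternative-source arboreal flag) to a single category. Rules:
#' under `-Mc-` schemes a set `mcentire_arboreal` flag forces `A`;
#' under `-L` schemes a terrestrial primary is overridden by a
#' non-terrestrial secondary; under `-M` schemes the primary wins;
#' under `7-` schemes `SW` is preserved, under `6-` schemes it is
#' remapped to the per-species `sw_override` (default `W`), since the
#' aquatic-vs-other resolution is a natural-history fact, not a rule.
#'
#' @param primary primary microhabitat code(s), in
#'   [microhabitat_codes()].
#' @param secondary secondary code(s) or `NA`.
#' @param mcentire_arboreal logical flag(s): species listed as arboreal
#'   by the alternative source.
#' @param sw_override per-species remap target for SW under 6-category
#'   schemes (one of A, C, F, S, T, W).
#' @param scheme one of [microhabitat_schemes()].
#' @return Character vector of categories, each within the scheme's
#'   permitted set.
#' @export
classify_microhabitat <- function(primary, secondary = NA,
                                  mcentire_arboreal = FALSE,
                                  sw_override = "W", scheme) {
  scheme <- match.arg(scheme, microhabitat_schemes())
  n <- length(primary)
  secondary <- rep_len(secondary, n)
  mcentire_arboreal <- rep_len(mcentire_arboreal, n)
  sw_override <- rep_len(sw_override, n)
  sw_override[is.na(sw_override)] <- "W"
  codes <- microhabitat_codes()
  if (!all(primary %in% codes))
    stop("unknown primary code: ",
         paste(unique(setdiff(primary, codes)), collapse = ", "))
  sec_known <- is.na(secondary) | secondary %in% codes
  if (!all(sec_known))
    stop("unknown secondary code: ",
         paste(unique(secondary[!sec_known]), collapse = ", "))
  if (!all(sw_override %in% setdiff(codes, "SW")))
    stop("sw_override must be one of A, C, F, S, T, W")

  lenient <- endsWith(scheme, "L")
  seven <- startsWith(scheme, "7")
  mc <- grepl("Mc", scheme, fixed = TRUE)

  out <- primary
  if (lenient) {
    hit <- out == "T" & !is.na(secondary) & secondary != "T"
    out[hit] <- secondary[hit]
  }
  if (!seven) {
    sw <- out == "SW"
    out[sw] <- sw_override[sw]
  }
  if (mc) out[mcentire_arboreal %in% TRUE] <- "A"
  allowed <- if (seven) codes else setdiff(codes, "SW")
  stopifnot(all(out %in% allowed))
  out
}

#' Classify a microhabitat table under all (or selected) schemes
#'
#' @param records data frame with columns `species`, `primary`, and
#'   optionally `secondary`, `mcentire_arboreal`, `sw_override`.
#' @param schemes scheme identifiers; defaults to all six.
#' @return Wide data frame: `species` plus one category column per
#'   scheme.
#' @export
classify_table <- function(records, schemes = microhabitat_schemes()) {
  stopifnot(all(c("species", "primary") %in% names(records)))
  secondary <- if ("secondary" %in% names(records)) records$secondary else NA
  flag <- if ("mcentire_arboreal" %in% names(records))
    records$mcentire_arboreal else FALSE
  ovr <- if ("sw_override" %in% names(records)) records$sw_override else "W"
  out <- data.frame(species = records$species)
  for (s in schemes)
    out[[s]] <- classify_microhabitat(records$primary, secondary, flag,
                                      ovr, scheme = s)
  out
}
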