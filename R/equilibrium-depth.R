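#' Registry of calcite-water oxygen-isotope paleotemperature equations
#'
#' Quadratic paleotemperature forms T = A - B*D + C*D^2, where
#' D = d18O_c(VPDB) - (d18O_sw(VSMOW) - adj) and `adj` is the VSMOW-to-VPDB
#' adjustment for the acid-liberated CO2 comparison. The default
#' `"oneil_shackleton"` entry is the Shackleton (1974) refit of the O'Neil et
#' al. (1969) inorganic-calcite experiments (A = 16.9, B = 4.38, C = 0.10)
#' with a 0.27 permil adjustment.
#'
#' @format A named list; each entry has elements `A`, `B`, `C`, `adj`.
#' @export
paleotemp_equations <- list(
  oneil_shackleton = list(A = 16.9, B = 4.38, C = 0.10, adj = 0.27)
)

get_paleotemp_eq <- function(equation) {
  if (is.list(equation) && all(c("A", "B", "C", "adj") %in% names(equation))) {
    return(equation)
  }
  if (is.character(equation) && equation %in% names(paleotemp_equations)) {
    return(paleotemp_equations[[equation]])
  }
  abort(paste0("unknown paleotemperature equation: ",
               paste(equation, collapse = ", ")))
}

#' Equilibrium calcite d18O at a given temperature and seawater d18O
#'
#' Inverts the quadratic paleotemperature equation
#' T = A - B*D + C*D^2 for D and returns
#' d18O_c = D + d18O_sw - adj on the VPDB scale, taking the physically
#' meaningful (smaller) root. An optional vital-effect offset can be added
#' for datasets where a species-specific disequilibrium is warranted; the
#' default is no offset.
#'
#' @param temperature Calcification temperature, degrees C (vectorized).
#' @param d18Osw Seawater d18O, permil VSMOW (vectorized).
#' @param equation Name in [paleotemp_equations] or an equivalent list.
#' @param vital_effect Additive offset on the returned calcite d18O, permil
#'   (default 0).
#' @return Equilibrium calcite d18O, permil VPDB.
#' @examples
#' equilibrium_d18Oc(0, 0.27)   # ~4.28 permil
#' equilibrium_d18Oc(16.9, 0.27) # 0
#' @export
equilibrium_d18Oc <- function(temperature, d18Osw,
                              equation = "oneil_shackleton",
                              vital_effect = 0) {
  eq <- get_paleotemp_eq(equation)
  disc <- eq$B^2 - 4 * eq$C * (eq$A - temperature)
  if (any(disc < 0, na.rm = TRUE)) {
    abort(sprintf(
      "equilibrium_d18Oc(): temperature below the quadratic's minimum (%.2f C); no real root",
      eq$A - eq$B^2 / (4 * eq$C)))
  }
  delta <- (eq$B - sqrt(disc)) / (2 * eq$C)
  delta + d18Osw - eq$adj + vital_effect
}

#' Temperature from calcite and seawater d18O (forward quadratic)
#'
#' Evaluates T = A - B*D + C*D^2 with
#' D = d18O_c - (d18O_sw - adj); the forward companion of
#' [equilibrium_d18Oc()].
#'
#' @inheritParams equilibrium_d18Oc
#' @param d18Oc Calcite d18O, permil VPDB.
#' @return Temperature, degrees C.
#' @export
paleotemp_temperature <- function(d18Oc, d18Osw,
                                  equation = "oneil_shackleton") {
  eq <- get_paleotemp_eq(equation)
  delta <- d18Oc - (d18Osw - eq$adj)
  eq$A - eq$B * delta + eq$C * delta^2
}

#' Equilibrium calcite d18O along a water-column profile
#'
#' Computes the expected equilibrium calcite d18O at every profile level from
#' temperature and seawater d18O. Seawater d18O is taken from the profile's
#' `d18Osw_permil` column where present, otherwise predicted from salinity
#' through a fitted mixing line.
#'
#' @param profile A hydrographic profile tibble with `depth_m`, `temp_C`,
#'   `sal` and optionally `d18Osw_permil`.
#' @param mixing_line Optional [fit_d18Osw_salinity()] result used to fill
#'   missing seawater d18O from salinity.
#' @inheritParams equilibrium_d18Oc
#' @return A tibble `depth_m`, `d18Oc_eq_permil`, `d18Osw_permil`.
#' @export
equilibrium_profile <- function(profile, mixing_line = NULL,
                                equation = "oneil_shackleton",
                                vital_effect = 0) {
  profile <- validate_profile_levels(profile)
  if (!"temp_C" %in% names(profile)) {
    abort("equilibrium_profile(): profile must have a temp_C column")
  }
  d18Osw <- if ("d18Osw_permil" %in% names(profile)) {
    profile$d18Osw_permil
  } else {
    rep(NA_real_, nrow(profile))
  }
  miss <- !is.finite(d18Osw)
  if (any(miss)) {
    if (is.null(mixing_line)) {
      abort(paste0("equilibrium_profile(): levels without d18Osw_permil and ",
                   "no salinity mixing line supplied"))
    }
    d18Osw[miss] <- predict_d18Osw(mixing_line, profile$sal[miss])
  }
  tibble(
    depth_m = profile$depth_m,
    d18Oc_eq_permil = equilibrium_d18Oc(profile$temp_C, d18Osw,
                                        equation, vital_effect),
    d18Osw_permil = d18Osw
  )
}

#' Infer apparent calcification depth from measured calcite d18O
#'
#' Finds the depth(s) at which the piecewise-linear equilibrium calcite d18O
#' curve crosses each measured value and reports the shallowest crossing along
#' with linearly interpolated temperature, salinity, carbonate ion and
#' seawater d18O at that depth. When the equilibrium curve is non-monotone the
#' number of crossings is reported in `ambiguity_count`; values that never
#' cross return `matched = FALSE` (fossil or transported material can
#' legitimately fall outside the modern water column). Estimates deeper than
#' `suspect_below` are flagged `suspect_deep` because they usually indicate a
#' profile warmer than the calcification environment.
#'
#' @param measured_d18Oc Measured foraminiferal calcite d18O, permil VPDB
#'   (vectorized).
#' @param eq An [equilibrium_profile()] tibble.
#' @param profile The matching hydrographic profile (same depth grid).
#' @param suspect_below Depth in m beyond which a match is flagged suspect
#'   (default 300).
#' @return A tibble, one row per measurement: `measured_d18Oc`, `depth_m`,
#'   `temp_C`, `sal`, `co3_umolkg`, `d18Osw_permil`, `matched`,
#'   `ambiguity_count`, `suspect_deep`.
#' @export
infer_calcification_depth <- function(measured_d18Oc, eq, profile,
                                      suspect_below = 300) {
  eq <- validate_profile_levels(eq)
  profile <- validate_profile_levels(profile)
  if (!isTRUE(all.equal(eq$depth_m, profile$depth_m))) {
    abort("infer_calcification_depth(): eq and profile must share a depth grid")
  }
  purrr::map_dfr(measured_d18Oc, function(v) {
    cr <- curve_crossings(eq$depth_m, eq$d18Oc_eq_permil, v)
    if (length(cr) == 0) {
      return(tibble(measured_d18Oc = v, depth_m = NA_real_, temp_C = NA_real_,
                    sal = NA_real_, co3_umolkg = NA_real_,
                    d18Osw_permil = NA_real_, matched = FALSE,
                    ambiguity_count = 0L, suspect_deep = FALSE))
    }
    z <- min(cr) # shallowest crossing: shallow-habitat ecology, never averaged
    env <- profile_interpolate(profile, z)
    tibble(
      measured_d18Oc = v,
      depth_m = z,
      temp_C = env$temp_C %||% NA_real_,
      sal = if ("sal" %in% names(env)) env$sal else NA_real_,
      co3_umolkg = if ("co3_umolkg" %in% names(env)) env$co3_umolkg else NA_real_,
      d18Osw_permil = if ("d18Osw_permil" %in% names(env)) env$d18Osw_permil else NA_real_,
      matched = TRUE,
      ambiguity_count = length(cr),
      suspect_deep = z > suspect_below
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All depths where the piecewise-linear curve (x, y) equals value v.
curve_crossings <- function(x, y, v) {
  out <- x[which(y == v)]
  dy <- diff(y)
  for (i in seq_len(length(x) - 1)) {
    y0 <- y[i]; y1 <- y[i + 1]
    if ((y0 < v && y1 > v) || (y0 > v && y1 < v)) {
      out <- c(out, x[i] + (v - y0) / (y1 - y0) * (x[i + 1] - x[i]))
    }
  }
  sort(unique(out))
}
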