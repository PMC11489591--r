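#' Solve the seawater carbonate system from alkalinity and DIC
#'
#' Computes carbonate-ion concentration, pH (total scale) and calcite
#' saturation state from a total alkalinity / dissolved inorganic carbon pair
#' at given salinity, temperature and pressure. The dissociation constants are
#' the de-facto standard set of CO2SYS-family tools: K1/K2 of Lueker et
#' al. (2000) on the total pH scale, boric acid after Dickson (1990), water
#' after Millero (1995), bisulfate after Dickson (1990), fluoride after
#' Dickson & Riley (1979), total boron from salinity after Uppstrom (1974),
#' and the Mucci (1983) calcite solubility product, all with standard Millero
#' (1995) pressure corrections. Equilibrium is found by root-bracketing on pH
#' in [6, 9.5] to a tolerance of 1e-8 pH units.
#'
#' Nutrient (phosphate/silicate) alkalinity contributions are not modelled;
#' for the oligotrophic-to-subpolar surface waters this package targets their
#' neglect changes carbonate ion by well under a percent.
#'
#' @param alk Total alkalinity, umol/kg.
#' @param dic Dissolved inorganic carbon, umol/kg.
#' @param salinity Practical salinity, in (0, 45).
#' @param temperature In-situ temperature, degrees C, in (-3, 40).
#' @param pressure Hydrostatic pressure, dbar (0 at the surface).
#' @param solver Optional replacement solver function with the same signature
#'   returning a data frame of `co3`, `ph_total`, `omega_calcite`; an adapter
#'   seam for plugging in an external full-featured carbonate-system package.
#'
#' @return A tibble with one row per input: `co3` (umol/kg), `ph_total`,
#'   `omega_calcite`.
#' @examples
#' solve_carbonate(2300, 2100, 35, 10)
#' @export
solve_carbonate <- function(alk, dic, salinity, temperature, pressure = 0,
                            solver = NULL) {
  if (!is.null(solver)) {
    return(as_tibble(solver(alk, dic, salinity, temperature, pressure)))
  }
  n <- max(length(alk), length(dic), length(salinity), length(temperature),
           length(pressure))
  alk <- rep_len(alk, n); dic <- rep_len(dic, n)
  salinity <- rep_len(salinity, n); temperature <- rep_len(temperature, n)
  pressure <- rep_len(pressure, n)

  bad <- !is.finite(alk) | !is.finite(dic) | alk <= 0 | dic <= 0
  if (any(bad)) {
    abort(sprintf("solve_carbonate(): alk and dic must be positive and finite (rows %s)",
                  paste(which(bad), collapse = ", ")))
  }
  if (any(salinity <= 0 | salinity >= 45)) {
    abort("solve_carbonate(): salinity must lie in (0, 45)")
  }
  if (any(temperature <= -3 | temperature >= 40)) {
    abort("solve_carbonate(): temperature must lie in (-3, 40) degrees C")
  }
  if (any(pressure < 0)) abort("solve_carbonate(): pressure must be >= 0 dbar")

  out <- purrr::map(seq_len(n), function(i) {
    solve_carbonate_one(alk[i] * 1e-6, dic[i] * 1e-6, salinity[i],
                        temperature[i], pressure[i])
  })
  tibble(
    co3 = purrr::map_dbl(out, "co3") * 1e6,
    ph_total = purrr::map_dbl(out, "ph_total"),
    omega_calcite = purrr::map_dbl(out, "omega_calcite")
  )
}

# Equilibrium constants on the total pH scale (mol/kg-SW), with pressure
# corrections after Millero (1995). S practical, TC deg C, P dbar.
carb_constants <- function(S, TC, P = 0) {
  TK <- TC + 273.15
  lnTK <- log(TK)
  IS <- 19.924 * S / (1000 - 1.005 * S)

  TB <- 0.0004157 * S / 35          # Uppstrom (1974)
  TS <- 0.14 / 96.062 * S / 1.80655 # Morris & Riley (1966)
  TF <- 0.000067 / 18.998 * S / 1.80655 # Riley (1965)

  # Lueker et al. (2000), total scale (pK on log10 basis)
  K1 <- 10^-(3633.86 / TK - 61.2172 + 9.6777 * lnTK -
               0.011555 * S + 0.0001152 * S^2)
  K2 <- 10^-(471.78 / TK + 25.9290 - 3.16967 * lnTK -
               0.01781 * S + 0.0001122 * S^2)

  # Dickson (1990a), total scale
  KB <- exp((-8966.90 - 2890.53 * sqrt(S) - 77.942 * S +
               1.728 * S^1.5 - 0.0996 * S^2) / TK +
              148.0248 + 137.1942 * sqrt(S) + 1.62142 * S +
              (-24.4344 - 25.085 * sqrt(S) - 0.2474 * S) * lnTK +
              0.053105 * sqrt(S) * TK)

  # Dickson (1990b), free scale
  KS <- exp(-4276.1 / TK + 141.328 - 23.093 * lnTK +
              (-13856 / TK + 324.57 - 47.986 * lnTK) * sqrt(IS) +
              (35474 / TK - 771.54 + 114.723 * lnTK) * IS -
              2698 / TK * IS^1.5 + 1776 / TK * IS^2 +
              log(1 - 0.001005 * S))

  # Dickson & Riley (1979), free scale
  KF <- exp(1590.2 / TK - 12.641 + 1.525 * sqrt(IS) + log(1 - 0.001005 * S))

  # Millero (1995) on the seawater scale, converted to total
  KW_sws <- exp(148.9802 - 13847.26 / TK - 23.6521 * lnTK +
                  (118.67 / TK - 5.977 + 1.0495 * lnTK) * sqrt(S) -
                  0.01615 * S)
  sws2tot <- (1 + TS / KS) / (1 + TS / KS + TF / KF)
  KW <- KW_sws * sws2tot

  # Mucci (1983) calcite solubility
  Ksp <- 10^(-171.9065 - 0.077993 * TK + 2839.319 / TK +
               71.595 * log10(TK) +
               (-0.77712 + 0.0028426 * TK + 178.34 / TK) * sqrt(S) -
               0.07711 * S + 0.0041249 * S^1.5)

  if (P > 0) {
    Pbar <- P / 10
    Rgas <- 83.14462618
    pc <- function(K, dV, dK) K * exp((-dV + 0.5 * dK * Pbar) * Pbar / (Rgas * TK))
    K1  <- pc(K1, -25.50 + 0.1271 * TC, (-3.08 + 0.0877 * TC) / 1000)
    K2  <- pc(K2, -15.82 - 0.0219 * TC, (1.13 - 0.1475 * TC) / 1000)
    KB  <- pc(KB, -29.48 + 0.1622 * TC - 0.002608 * TC^2, -2.84 / 1000)
    KW  <- pc(KW, -20.02 + 0.1119 * TC - 0.001409 * TC^2,
              (-5.13 + 0.0794 * TC) / 1000)
    KS  <- pc(KS, -18.03 + 0.0466 * TC + 0.000316 * TC^2,
              (-4.53 + 0.09 * TC) / 1000)
    KF  <- pc(KF, -9.78 - 0.0090 * TC - 0.000942 * TC^2,
              (-3.91 + 0.054 * TC) / 1000)
    Ksp <- pc(Ksp, -48.76 + 0.5304 * TC, (-11.76 + 0.3692 * TC) / 1000)
  }

  Ca <- 0.02128 / 40.087 * S / 1.80655
  list(K1 = K1, K2 = K2, KB = KB, KS = KS, KF = KF, KW = KW,
       Ksp = Ksp, TB = TB, TS = TS, TF = TF, Ca = Ca)
}

# Total alkalinity (mol/kg) implied by total-scale [H+] at fixed DIC.
alkalinity_at_ph <- function(H, dic, k) {
  Hfree <- H / (1 + k$TS / k$KS)
  den <- H^2 + k$K1 * H + k$K1 * k$K2
  hco3 <- dic * k$K1 * H / den
  co3 <- dic * k$K1 * k$K2 / den
  balk <- k$TB * k$KB / (k$KB + H)
  oh <- k$KW / H
  hso4 <- k$TS * Hfree / (k$KS + Hfree)
  hf <- k$TF * Hfree / (k$KF + Hfree)
  list(ta = hco3 + 2 * co3 + balk + oh - Hfree - hso4 - hf, co3 = co3)
}

solve_carbonate_one <- function(alk, dic, S, TC, P) {
  k <- carb_constants(S, TC, P)
  f <- function(ph) alkalinity_at_ph(10^-ph, dic, k)$ta - alk
  flo <- f(6); fhi <- f(9.5)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    abort(sprintf(paste0("solve_carbonate(): no pH root in [6, 9.5] for ",
                         "alk=%.1f umol/kg, dic=%.1f umol/kg, S=%.2f, T=%.2f C"),
                  alk * 1e6, dic * 1e6, S, TC))
  }
  root <- stats::uniroot(f, c(6, 9.5), tol = 1e-8)
  ph <- root$root
  st <- alkalinity_at_ph(10^-ph, dic, k)
  list(co3 = st$co3, ph_total = ph,
       omega_calcite = st$co3 * k$Ca / k$Ksp)
}

#' Fit a local seawater d18O - salinity mixing line
#'
#' Ordinary least squares of seawater d18O on salinity, the site-specific
#' relationship used to extend spot d18O_sw measurements to a full water
#' column. Freshwater end-members (ice melt, runoff) make this line strongly
#' regional, hence one line per core site.
#'
#' @param data A data frame with columns `sal` and `d18Osw_permil`
#'   (VSMOW), one row per paired measurement.
#' @return An object of class `salinity_mixing_line`: slope (permil per
#'   salinity unit), intercept (permil VSMOW), `n_points`, `rmse`.
#' @examples
#' fit_d18Osw_salinity(data.frame(sal = c(33, 34, 35),
#'                                d18Osw_permil = c(-0.5, 0, 0.5)))
#' @export
fit_d18Osw_salinity <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("sal", "d18Osw_permil")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("fit_d18Osw_salinity(): missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  data <- data[is.finite(data$sal) & is.finite(data$d18Osw_permil), , drop = FALSE]
  if (nrow(data) < 2) abort("fit_d18Osw_salinity(): need at least 2 points")
  if (length(unique(data$sal)) < 2) {
    abort("fit_d18Osw_salinity(): degenerate fit, all salinities identical")
  }
  fit <- lm(d18Osw_permil ~ sal, data = data)
  structure(
    list(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         n_points = nrow(data),
         rmse = sqrt(mean(resid(fit)^2))),
    class = "salinity_mixing_line"
  )
}

#' Predict seawater d18O from salinity with a fitted mixing line
#'
#' @param line A `salinity_mixing_line`.
#' @param sal Practical salinity (vectorized).
#' @return d18O_sw, permil VSMOW.
#' @export
predict_d18Osw <- function(line, sal) {
  stopifnot(inherits(line, "salinity_mixing_line"))
  line$intercept + line$slope * sal
}

#' @export
print.salinity_mixing_line <- function(x, ...) {
  cat(sprintf("d18O_sw = %.4f * S %+.4f  (n = %d, rmse = %.4f permil)\n",
              x$slope, x$intercept, x$n_points, x$rmse))
  invisible(x)
}

#' @method tidy salinity_mixing_line
#' @export
tidy.salinity_mixing_line <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept))
}

#' @method glance salinity_mixing_line
#' @export
glance.salinity_mixing_line <- function(x, ...) {
  tibble(n_points = x$n_points, rmse = x$rmse)
}

#' Interpolate a hydrographic profile at arbitrary depth
#'
#' Linear interpolation of every numeric column of a depth-ordered profile
#' between the bracketing levels; exact at grid nodes. Depths outside the
#' sampled grid raise an error rather than extrapolating.
#'
#' @param profile A data frame with a strictly increasing `depth_m` column and
#'   any number of numeric level columns (e.g. `temp_C`, `sal`, `alk_umolkg`).
#' @param depth Target depth(s), m.
#' @return A tibble with one row per requested depth.
#' @export
profile_interpolate <- function(profile, depth) {
  profile <- validate_profile_levels(profile)
  rng <- range(profile$depth_m)
  if (any(depth < rng[1] | depth > rng[2])) {
    abort(sprintf(
      "profile_interpolate(): depth outside sampled grid [%g, %g] m; refusing to extrapolate",
      rng[1], rng[2]))
  }
  numcols <- names(profile)[vapply(profile, is.numeric, logical(1))]
  numcols <- setdiff(numcols, "depth_m")
  out <- tibble(depth_m = depth)
  for (cl in numcols) {
    y <- profile[[cl]]
    ok <- is.finite(y)
    out[[cl]] <- if (sum(ok) >= 2) {
      approx(profile$depth_m[ok], y[ok], xout = depth)$y
    } else if (sum(ok) == 1) {
      ifelse(depth == profile$depth_m[ok], y[ok], NA_real_)
    } else {
      NA_real_
    }
  }
  out
}

validate_profile_levels <- function(profile) {
  stopifnot(is.data.frame(profile))
  if (!"depth_m" %in% names(profile)) {
    abort("profile must have a depth_m column")
  }
  profile <- as_tibble(profile)
  if (is.unsorted(profile$depth_m, strictly = TRUE)) {
    abort("profile depths must be strictly increasing")
  }
  profile
}

#' Fill carbonate-ion concentrations along a profile
#'
#' Populates missing `co3_umolkg` values from `alk_umolkg`/`dic_umolkg` pairs
#' via [solve_carbonate()], treating depth as pressure (1 m ~ 1 dbar). Levels
#' that already carry a carbonate-ion value are left untouched.
#'
#' @param profile A hydrographic profile tibble (see [read_profile()]).
#' @param use_depth_pressure Apply in-situ pressure corrections using the
#'   level depth (default TRUE); FALSE fixes surface pressure.
#' @return The profile with `co3_umolkg` filled where derivable.
#' @export
profile_carbonate <- function(profile, use_depth_pressure = TRUE) {
  profile <- validate_profile_levels(profile)
  if (!"co3_umolkg" %in% names(profile)) profile$co3_umolkg <- NA_real_
  need <- which(!is.finite(profile$co3_umolkg) &
                  is.finite(profile$alk_umolkg) &
                  is.finite(profile$dic_umolkg))
  if (length(need)) {
    p <- if (use_depth_pressure) profile$depth_m[need] else 0
    st <- solve_carbonate(profile$alk_umolkg[need], profile$dic_umolkg[need],
                          profile$sal[need], profile$temp_C[need], p)
    profile$co3_umolkg[need] <- st$co3
  }
  profile
}
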