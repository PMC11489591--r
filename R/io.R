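#' Read a geochemical sample table
#'
#' CSV dialect: UTF-8, header row, '.' decimal, empty cell = absent. Columns
#' `sample_id`, `mgca_mmolmol`, `d18Oc_permil`, `source` (tow / coretop /
#' trap / downcore), `crust_state` (ontogenetic / crusted / unknown),
#' `cleaning` (oxidative / reductive / unknown), `size_fraction_um`,
#' `temp_C`, `co3_umolkg`, `sal`, `d18Osw_permil`. At least one of the two
#' proxy columns must exist; rows failing validation (e.g. negative Mg/Ca)
#' are dropped with a warning naming their line numbers, the rest load.
#'
#' @param path CSV path.
#' @return A validated sample tibble.
#' @export
read_samples <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!any(c("mgca_mmolmol", "d18Oc_permil") %in% names(x))) {
    abort(paste0("read_samples(): need at least one of the columns ",
                 "mgca_mmolmol, d18Oc_permil in ", path))
  }
  if (!"mgca_mmolmol" %in% names(x)) x$mgca_mmolmol <- NA_real_
  if (!"d18Oc_permil" %in% names(x)) x$d18Oc_permil <- NA_real_
  if (!"crust_state" %in% names(x)) x$crust_state <- "unknown"
  if (!"cleaning" %in% names(x)) x$cleaning <- "unknown"
  if (!"source" %in% names(x)) x$source <- "unknown"
  bad_empty <- !is.finite(x$mgca_mmolmol) & !is.finite(x$d18Oc_permil)
  bad_neg <- is.finite(x$mgca_mmolmol) & x$mgca_mmolmol <= 0
  bad <- bad_empty | bad_neg
  if (any(bad)) {
    warn(sprintf("read_samples(): dropped %d invalid row(s) (file lines %s): %s",
                 sum(bad),
                 paste(which(bad) + 1L, collapse = ", "),
                 paste(unique(c(if (any(bad_empty)) "both proxies absent",
                                if (any(bad_neg)) "non-positive Mg/Ca")),
                       collapse = "; ")))
    x <- x[!bad, , drop = FALSE]
  }
  x
}

#' Read a hydrographic profile table
#'
#' CSV columns: `station_id`, `lat`, `lon`, `date` (ISO-8601), `depth_m`,
#' `temp_C`, `sal`, `alk_umolkg`, `dic_umolkg`, `d18Osw_permil`,
#' `co3_umolkg`; empty cells mean absent. Depths must be strictly increasing
#' within each station; salinity in (0, 45) and temperature in (-3, 40)
#' where present.
#'
#' @param path CSV path.
#' @param station Optional station_id to select (required when the file
#'   holds several stations and a single profile is wanted).
#' @return A validated profile tibble, depth-ordered.
#' @export
read_profile <- function(path, station = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("station_id", "depth_m", "temp_C", "sal")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("read_profile(): missing columns: ",
                 paste(miss, collapse = ", "), " in ", path))
  }
  for (cl in c("alk_umolkg", "dic_umolkg", "d18Osw_permil", "co3_umolkg")) {
    if (!cl %in% names(x)) x[[cl]] <- NA_real_
  }
  if (!is.null(station)) {
    x <- x[x$station_id == station, , drop = FALSE]
    if (nrow(x) == 0) abort(paste0("read_profile(): no station ", station))
  }
  bad_sal <- is.finite(x$sal) & (x$sal <= 0 | x$sal >= 45)
  bad_t <- is.finite(x$temp_C) & (x$temp_C <= -3 | x$temp_C >= 40)
  bad <- bad_sal | bad_t
  if (any(bad)) {
    abort(sprintf("read_profile(): out-of-range salinity/temperature at file line(s) %s",
                  paste(which(bad) + 1L, collapse = ", ")))
  }
  x <- dplyr::arrange(x, .data$station_id, .data$depth_m)
  for (st in unique(x$station_id)) {
    d <- x$depth_m[x$station_id == st]
    if (anyDuplicated(d)) {
      abort(paste0("read_profile(): duplicated depths for station ", st))
    }
  }
  x
}

#' Read a downcore paired proxy record
#'
#' CSV columns: `core_id`, `age_ka`, `mgca_mmolmol`, `d18Oc_permil`,
#' `cleaning`, `crust_state`. Ages must be non-decreasing.
#'
#' @param path CSV path.
#' @return A validated record tibble.
#' @export
read_record <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("age_ka", "mgca_mmolmol", "d18Oc_permil")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("read_record(): missing columns: ",
                 paste(miss, collapse = ", "), " in ", path))
  }
  if (is.unsorted(x$age_ka)) {
    abort("read_record(): ages must be non-decreasing")
  }
  bad <- is.finite(x$mgca_mmolmol) & x$mgca_mmolmol <= 0
  if (any(bad)) {
    warn(sprintf("read_record(): dropped %d row(s) with non-positive Mg/Ca (file lines %s)",
                 sum(bad), paste(which(bad) + 1L, collapse = ", ")))
    x <- x[!bad, , drop = FALSE]
  }
  x
}

#' Write any result tibble to CSV
#'
#' @param x A tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outputs <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Serialise a calibration model to a flat YAML file
#'
#' Writes the fitted coefficient set (corrected exponential law, power-law
#' sensitivity, d18O proxy line, prediction law) with their 2-sigma
#' uncertainties, n and r-squared as a flat key-value YAML document.
#'
#' @param model A [calibration_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  num <- function(v) if (is.null(v) || !is.finite(v)) NA else v
  x <- list(
    a = model$exp_law$a, b = model$exp_law$b,
    a_se2 = num(model$exp_law$a_se), b_se2 = num(model$exp_law$b_se),
    exp_n = num(model$exp_law$n), exp_r2 = num(model$exp_law$r2),
    p = model$power_law$p, q = model$power_law$q,
    p_se2 = num(model$power_law$p_se), q_se2 = num(model$power_law$q_se),
    power_n = num(model$power_law$n), power_r2 = num(model$power_law$r2),
    pred_a = model$pred_law$a, pred_b = model$pred_law$b
  )
  if (!is.null(model$oxy_line)) {
    x$oxy_slope <- model$oxy_line$slope
    x$oxy_slope_se2 <- num(model$oxy_line$slope_se)
    x$oxy_intercept_ontogenetic <- num(model$oxy_line$intercept_ontogenetic)
    x$oxy_intercept_crusted <- num(model$oxy_line$intercept_crusted)
    x$oxy_n <- num(model$oxy_line$n)
  }
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a calibration model from a flat YAML file
#'
#' @param path Path written by [write_calibration_model()] (or hand-authored
#'   with the same keys; intercept keys may be omitted when no d18O proxy
#'   line is available).
#' @return A [calibration_model()].
#' @export
read_calibration_model <- function(path) {
  x <- yaml::read_yaml(path)
  num <- function(v) if (is.null(v) || !length(v) || is.na(v)) NA_real_ else as.numeric(v)
  elaw <- mgca_exp_law(x$a, x$b, a_se = num(x$a_se2), b_se = num(x$b_se2),
                       n = as.integer(num(x$exp_n)), r2 = num(x$exp_r2))
  plaw <- mgca_power_law(x$p, x$q, p_se = num(x$p_se2), q_se = num(x$q_se2),
                         n = as.integer(num(x$power_n)), r2 = num(x$power_r2))
  oline <- NULL
  if (!is.null(x$oxy_slope)) {
    oline <- oxy_carb_line(x$oxy_slope,
                           intercept_ontogenetic = num(x$oxy_intercept_ontogenetic),
                           intercept_crusted = num(x$oxy_intercept_crusted),
                           n = as.integer(num(x$oxy_n)),
                           slope_se = num(x$oxy_slope_se2))
  }
  pred <- if (!is.null(x$pred_a)) mgca_exp_law(x$pred_a, x$pred_b)
          else mgca_pred_law()
  calibration_model(elaw, plaw, oline, pred)
}
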