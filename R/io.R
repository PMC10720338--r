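# Readers and writers: plain two-column profile tables and the GROMACS .xvg
# density-profile dialect, experimental osmotic-coefficient tables, LJ
# parameter tables, and the JSON fit report.

REPORT_SCHEMA_VERSION <- "1.0"

#' Read a z-binned concentration profile from a text table
#'
#' Supported dialects: \code{"plain-tsv"} (whitespace-separated two-column
#' numeric table, comment lines starting with '#') and \code{"xvg"}
#' (GROMACS analysis output: lines starting with '#' or '@' are skipped).
#' Column units must be declared explicitly; no silent defaults.
#'
#' @param path File path.
#' @param box A [box_spec()].
#' @param restraint A [restraint_spec()].
#' @param dialect \code{"plain-tsv"} or \code{"xvg"}.
#' @param z_unit \code{"A"} or \code{"nm"} (nm is converted to Angstrom).
#' @param value_unit \code{"M"} (molarity) or \code{"number-density"}
#'   (count per nm^3, converted to M).
#' @param N_s Optional formula-unit count attached to the profile.
#' @return A [concentration_profile()].
#' @export
read_profile <- function(path, box, restraint,
                         dialect = c("plain-tsv", "xvg"),
                         z_unit = c("A", "nm"),
                         value_unit = c("M", "number-density"),
                         N_s = NULL) {
  dialect <- match.arg(dialect)
  z_unit <- match.arg(z_unit)
  value_unit <- match.arg(value_unit)
  if (!file.exists(path)) stop_domain("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  comment <- if (dialect == "xvg") grepl("^\\s*[#@]", lines) else
    grepl("^\\s*#", lines)
  keep <- !comment & nzchar(trimws(lines))
  if (!any(keep)) stop_domain("file contains no data rows: ", path)
  dat <- utils::read.table(text = lines[keep], header = FALSE,
                           colClasses = "numeric")
  if (ncol(dat) < 2) stop_domain("expected at least two numeric columns")
  z <- dat[[1]]; v <- dat[[2]]
  bad <- which(!is.finite(v) | v < 0)
  if (length(bad))
    stop_domain("invalid (NaN or negative) concentrations at data rows: ",
                paste(utils::head(bad, 10), collapse = ", "))
  if (z_unit == "nm") z <- z * 10
  if (value_unit == "number-density")
    v <- v / (osmo_constants$N_A * 1e-27) / 1000   # per nm^3 -> M
  dz <- diff(z)
  if (any(dz <= 0) || max(abs(dz - dz[1])) > 1e-6 * dz[1])
    stop_domain("non-uniform z grid in ", path,
                "; rebin the profile before analysis")
  concentration_profile(z, v, box, restraint, N_s = N_s)
}

#' Write a profile (or pressure series) as a two-column text table
#'
#' @param x A [concentration_profile()] or a data.frame whose first two
#'   columns are written.
#' @param path Output path.
#' @param header Comment header line(s) written with a leading '#'.
#' @export
write_profile_table <- function(x, path, header = NULL) {
  if (inherits(x, "concentration_profile"))
    x <- data.frame(z_A = x$bin_centers, C_M = x$C_s)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste0("# ", paste(names(x)[1:2], collapse = "\t")), con)
  utils::write.table(x[, 1:2], con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an experimental osmotic-coefficient table
#'
#' CSV with a header naming a molality column (\code{m} or
#' \code{molality}) and an osmotic-coefficient column (\code{phi} or
#' \code{osmotic_coefficient}). The osmotic pressure is derived through
#' ln a_w = -nu M_w m phi and Pi = -RT ln a_w / Vbar_w.
#'
#' @param path CSV path.
#' @param salt A [salt_spec()].
#' @param solvent A [solvent_spec()].
#' @param Vbar_w Partial molar volume of water used in the pressure
#'   conversion, cm^3/mol (default: pure-water molar volume).
#' @return Data.frame with columns \code{m}, \code{phi}, \code{ln_aw},
#'   \code{Pi} (bar) and \code{C} (M, via the pure-water density mapping).
#' @export
read_eos_table <- function(path, salt, solvent,
                           Vbar_w = solvent$molar_mass_w / solvent$rho_w0) {
  if (!file.exists(path)) stop_domain("no such file: ", path)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  mcol <- intersect(c("m", "molality"), names(dat))[1]
  pcol <- intersect(c("phi", "osmotic_coefficient"), names(dat))[1]
  if (is.na(mcol) || is.na(pcol))
    stop_domain("header must name molality (m/molality) and ",
                "osmotic-coefficient (phi/osmotic_coefficient) columns")
  m <- dat[[mcol]]; phi <- dat[[pcol]]
  if (is.unsorted(m, strictly = TRUE))
    stop_domain("molality column must be strictly increasing")
  ln_aw <- -salt$nu * (solvent$molar_mass_w / 1000) * m * phi
  Pi <- -RT_kJ(solvent$temperature) * ln_aw / Vbar_w *
    osmo_constants$kJcm3_to_bar
  data.frame(m = m, phi = phi, ln_aw = ln_aw, Pi = Pi,
             C = molality_to_molarity(m, solvent$rho_w0, salt))
}

#' Read/write an LJ cross-interaction table
#'
#' CSV layout: salt, sigma_A, eps_K, chi, sigma_opt_A, eps_opt_K.
#'
#' @param path CSV path.
#' @return Data.frame in the layout above.
#' @export
read_lj_table <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("salt", "sigma_A", "eps_K", "chi")
  if (!all(need %in% names(dat)))
    stop_domain("LJ table must have columns: ", paste(need, collapse = ", "))
  dat
}

#' @rdname read_lj_table
#' @param tab Data.frame to write.
#' @export
write_lj_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

report_to_list <- function(report) {
  molal <- report$molal
  list(
    schema_version = REPORT_SCHEMA_VERSION,
    tool = list(name = "osmobalance", version = report$tool_version),
    salt = report$salt[c("name", "nu_plus", "nu_minus", "z_plus", "z_minus",
                         "molar_mass_salt")],
    solvent = unclass(report$solvent),
    molar = list(A_M_minushalf = report$molar$A, B_M_minushalf = report$molar$B,
                 alphas = as.list(report$molar$alphas)),
    molal = if (is.null(molal)) NULL else
      list(A_tilde_molal_minushalf = molal$A, B_tilde_molal_minushalf = molal$B,
           alphas_tilde = as.list(molal$alphas)),
    C_max_M = report$C_max,
    residual_norm_M = report$residual_norm,
    route_mse_bar2 = report$route_mse,
    floor_M = report$floor,
    electroneutrality_max_imbalance = report$electroneutrality,
    seed = report$seed,
    inputs = as.list(report$inputs)
  )
}

#' Serialize a fit report to JSON
#'
#' Writes a versioned-schema JSON document with unit-annotated keys; an
#' unset molal block is serialized as an explicit null.
#'
#' @param report A [fit_report()].
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "fit_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a fit report written by [write_report()]
#'
#' @param path JSON path.
#' @return A [fit_report()].
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema_version) ||
      x$schema_version != REPORT_SCHEMA_VERSION)
    stop_domain("report schema version mismatch: found ",
                if (is.null(x$schema_version)) "<none>" else x$schema_version,
                ", expected ", REPORT_SCHEMA_VERSION)
  salt <- salt_spec(x$salt$name, x$salt$nu_plus, x$salt$nu_minus,
                    x$salt$z_plus, x$salt$z_minus, x$salt$molar_mass_salt)
  solvent <- solvent_spec(x$solvent$dielectric, x$solvent$temperature,
                          x$solvent$rho_w0, x$solvent$molar_mass_w)
  molar <- moddh_molar(x$molar$A_M_minushalf, x$molar$B_M_minushalf,
                       unlist(x$molar$alphas))
  molal <- if (is.null(x$molal)) NULL else
    moddh_molal(x$molal$A_tilde_molal_minushalf,
                x$molal$B_tilde_molal_minushalf,
                unlist(x$molal$alphas_tilde))
  rep <- fit_report(molar = molar, molal = molal, C_max = x$C_max_M,
                    salt = salt, solvent = solvent,
                    residual_norm = x$residual_norm_M,
                    route_mse = if (is.null(x$route_mse_bar2)) NA_real_ else
                      x$route_mse_bar2,
                    floor = x$floor_M,
                    electroneutrality =
                      if (is.null(x$electroneutrality_max_imbalance))
                        NA_real_ else x$electroneutrality_max_imbalance,
                    seed = x$seed, inputs = unlist(x$inputs))
  rep$tool_version <- x$tool$version
  rep
}

#' Read a generator configuration from YAML
#'
#' Keys mirror the arguments of [generator_config()]; nested blocks
#' \code{salt}, \code{solvent}, \code{box}, \code{restraint} and
#' \code{params} hold the respective constructor arguments.
#'
#' @param path YAML path.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  generator_config(
    params = do.call(moddh_molar, y$params),
    salt = do.call(salt_spec, y$salt),
    solvent = do.call(solvent_spec, y$solvent),
    box = do.call(box_spec, y$box),
    restraint = do.call(restraint_spec, y$restraint),
    N_s = y$N_s, n_frames = y$n_frames,
    bin_width = y$bin_width, seed = y$seed)
}
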