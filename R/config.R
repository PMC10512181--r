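# Plain-text (YAML) configuration mirroring the subject, cardiac, and
# circulation parameter blocks, plus tabular/JSON exports of results.

#' Default model configuration
#'
#' Nested list with the subject block (normative healthy adult), cardiac
#' block (wall thicknesses, sarcomere and activation parameters,
#' pericardium), and circulation block (compartment fractions, viscoelastic
#' and valve resistances).  Written to and read from YAML by
#' [write_config()] / [read_config()].
#'
#' @return A nested list.
#' @export
default_config <- function() {
  s <- subject_data()
  list(
    subject = unclass(s),
    cardiac = list(h_LV = 0.8, h_RW = 0.4,
                   L_ref = 2, L_c0 = 1.51, L_se_iso = 0.04, v_max = 3.5,
                   gamma = 7.5, k_TS = 0.2, k_TR = 0.2,
                   pericardium_s = 10),
    circulation = list(fractions = compartment_fractions(),
                       Rt_SA = 0.08, Rt_PA = 0.02,
                       R_mv = 5e-4, R_tv = 5e-4))
}

#' Read a model configuration from YAML
#'
#' @param path Path to a YAML file with `subject`, `cardiac`, and
#'   `circulation` blocks; missing entries fall back to [default_config()].
#' @return A configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- default_config()
  merge_block <- function(user, defaults) {
    if (is.null(user)) return(defaults)
    defaults[names(user)] <- user
    defaults
  }
  out <- list(
    subject = merge_block(cfg$subject, def$subject),
    cardiac = merge_block(cfg$cardiac, def$cardiac),
    circulation = merge_block(cfg$circulation, def$circulation))
  if (is.list(out$circulation$fractions) &&
      !is.data.frame(out$circulation$fractions))
    out$circulation$fractions <-
      as.data.frame(out$circulation$fractions, stringsAsFactors = FALSE)
  out
}

#' Write a model configuration to YAML
#'
#' @param config A configuration list as from [default_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build model objects from a configuration
#'
#' @param config A configuration list as from [default_config()] or
#'   [read_config()].
#' @return List with `subject`, `sarc`, `h_LV`, `h_RW`, and circulation
#'   settings, ready for [calibrate_heart()] and
#'   [derive_circulation_parameters()].
#' @export
config_to_model <- function(config) {
  sub <- do.call(subject_data, config$subject[
    intersect(names(config$subject),
              names(formals(subject_data)))])
  cc <- config$cardiac
  sarc <- sarcomere_params(L_ref = cc$L_ref, L_c0 = cc$L_c0,
                           L_se_iso = cc$L_se_iso, v_max = cc$v_max,
                           gamma = cc$gamma)
  list(subject = sub, sarc = sarc, h_LV = cc$h_LV, h_RW = cc$h_RW,
       k_TS = cc$k_TS, k_TR = cc$k_TR,
       pericardium_s = cc$pericardium_s,
       circulation = config$circulation)
}

#' Export a simulation as tidy CSV with a JSON metrics sidecar
#'
#' Writes the recorded time series (time, per-compartment pressures and
#' volumes, valve flows, septal curvature and displacements) as CSV and the
#' per-beat metrics as JSON.
#'
#' @param sim A [simulate_heart()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
export_simulation <- function(sim, dir, prefix = "simulation") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, "_series.csv"))
  js <- file.path(dir, paste0(prefix, "_metrics.json"))
  utils::write.csv(sim$series, csv, row.names = FALSE)
  jsonlite::write_json(
    list(metrics = cardiac_metrics(sim),
         hr = sim$hr, tbv = sim$tbv,
         vol_conservation = sim$vol_conservation,
         periodicity = sim$periodicity),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(series = csv, metrics = js))
}
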