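#' Catalogue of in-silico perturbation experiments
#'
#' The ten named, parameter-free scenarios run against the canonical model:
#' \describe{
#'   \item{unperturbed}{stiffness input at 100 throughout.}
#'   \item{no_input}{stiffness input at 0 throughout.}
#'   \item{gradient_to_uniform}{input switched 100 -> 0 at t = 4000 s.}
#'   \item{uniform_to_gradient}{input switched 0 -> 100 at t = 4000 s.}
#'   \item{rhoa_kd}{RhoA moiety reduced to 12% of total at t = 0.}
#'   \item{caveolae_kd}{caveolae (Cav-1) moiety reduced to 12% at t = 0.}
#'   \item{osmotic_shock_reversible}{membrane-tension turnover raised
#'     1000-fold (0.01 -> 10) at t = 4000 s and restored (0.01) at
#'     t = 7000 s, mimicking hypo-osmotic shock and return to isotonic
#'     medium.}
#'   \item{y27632}{ROCK1 and PKN2 turnover raised 1000-fold (0.01 -> 10) at
#'     t = 5000 s, mimicking kinase inhibition.}
#'   \item{cytod_global}{F-actin to G-actin turnover raised 100-fold
#'     (0.01 -> 1) at t = 5000 s, mimicking bath cytochalasin-D.}
#'   \item{cytod_local}{F-actin turnover raised 20-fold (0.01 -> 0.2) at
#'     t = 5000 s, mimicking locally uncaged cytochalasin-D.}
#' }
#' Knockdown scenarios are initial-condition perturbations; drug and shock
#' scenarios are timed parameter events.
#'
#' @return named list of `rm_scenario` definitions with fields `name`,
#'   `input_value`, `knockdowns`, `events`, `observables`.
#' @export
scenario_catalog <- function() {
  obs <- c("RearRetraction", "ActinAlignment", "Caveolae")
  mk <- function(name, input_value = 100, knockdowns = list(), events = list())
    structure(list(name = name, input_value = input_value,
                   knockdowns = knockdowns, events = events,
                   observables = obs), class = "rm_scenario")
  list(
    unperturbed = mk("unperturbed"),
    no_input = mk("no_input", input_value = 0),
    gradient_to_uniform = mk("gradient_to_uniform", events = list(
      sim_event(4000, "set_species", "PolarizedSubstrateStiffness", 0))),
    uniform_to_gradient = mk("uniform_to_gradient", input_value = 0,
                             events = list(
      sim_event(4000, "set_species", "PolarizedSubstrateStiffness", 100))),
    rhoa_kd = mk("rhoa_kd", knockdowns = list(RhoA = 0.12)),
    caveolae_kd = mk("caveolae_kd", knockdowns = list(Caveolae = 0.12)),
    osmotic_shock_reversible = mk("osmotic_shock_reversible", events = list(
      sim_event(4000, "set_parameter", "kt_MembraneTension", 10),
      sim_event(7000, "set_parameter", "kt_MembraneTension", 0.01))),
    y27632 = mk("y27632", events = list(
      sim_event(5000, "set_parameter", "kt_ROCK1", 10),
      sim_event(5000, "set_parameter", "kt_PKN2", 10))),
    cytod_global = mk("cytod_global", events = list(
      sim_event(5000, "set_parameter", "kt_Actin", 1))),
    cytod_local = mk("cytod_local", events = list(
      sim_event(5000, "set_parameter", "kt_Actin", 0.2))))
}

#' Run one catalogue scenario
#'
#' Builds the initial state from the default initial conditions, applies the
#' scenario's input value and knockdowns, simulates with the scenario's
#' events and summarises the observables (final value and steady-state flag
#' each).
#'
#' @param name scenario name from [scenario_catalog()].
#' @param model an `rm_model`; the canonical model with default parameters
#'   when `NULL`.
#' @param settings an `rm_settings`.
#' @return an `rm_scenario_result`: `scenario`, `trajectory`, `observables`
#'   (named list of time series) and `summary` (`data.frame` with
#'   `observable`, `final`, `steady`).
#' @export
run_scenario <- function(name, model = NULL, settings = sim_settings()) {
  catalog <- scenario_catalog()
  if (!name %in% names(catalog))
    stop("unknown scenario '", name, "'; valid names: ",
         paste(names(catalog), collapse = ", "))
  sc <- catalog[[name]]
  if (is.null(model)) model <- compile_model()
  ics <- default_initial_conditions(model$wiring)
  ics[paste0(model$wiring$input_species, "_a")] <- sc$input_value
  ics[paste0(model$wiring$input_species, "_i")] <- 100 - sc$input_value
  for (nm in names(sc$knockdowns))
    ics <- apply_knockdown(ics, nm, sc$knockdowns[[nm]])
  traj <- simulate_model(model, ics, events = sc$events, settings = settings)
  series <- lapply(sc$observables, function(s) observable(traj, s))
  names(series) <- sc$observables
  ss <- steady_state(traj)
  summary <- data.frame(
    observable = sc$observables,
    final = vapply(series, function(s) s$value[nrow(s)], numeric(1)),
    steady = ss$converged,
    stringsAsFactors = FALSE)
  structure(list(scenario = sc, trajectory = traj, observables = series,
                 summary = summary), class = "rm_scenario_result")
}

#' @export
print.rm_scenario_result <- function(x, ...) {
  cat("scenario:", x$scenario$name, "\n")
  for (k in seq_len(nrow(x$summary)))
    cat(sprintf("  %-24s final %7.3f  %s\n", x$summary$observable[k],
                x$summary$final[k],
                if (x$summary$steady[k]) "(steady)" else "(not converged)"))
  invisible(x)
}

#' Divergence between two observable time series
#'
#' @param a,b `data.frame`s with `time` and `value` on the same grid.
#' @return list of class `rm_divergence`: `max_abs` (activity units),
#'   `rmse`, `t_max` (time of largest divergence, seconds).
#' @export
compare_trajectories <- function(a, b) {
  if (length(a$time) != length(b$time) || any(a$time != b$time))
    stop("time grids differ; divergence is defined on a shared grid")
  d <- abs(a$value - b$value)
  structure(list(max_abs = max(d),
                 rmse = sqrt(mean((a$value - b$value)^2)),
                 t_max = a$time[which.max(d)]),
            class = "rm_divergence")
}

#' Export a scenario result
#'
#' One CSV per observable (columns `time_s`, `value`) plus a JSON summary
#' with the scenario name, per-observable final values and steady flags,
#' and the divergence of each observable against the unperturbed run when
#' supplied.
#'
#' @param result an `rm_scenario_result`.
#' @param dir output directory (created if needed).
#' @param reference optional unperturbed `rm_scenario_result` for divergence.
#' @return paths of the files written, invisibly.
#' @export
export_scenario_result <- function(result, dir, reference = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(result$observables)) {
    p <- file.path(dir, paste0(result$scenario$name, "_", nm, ".csv"))
    s <- result$observables[[nm]]
    writeLines(c("time_s,value",
                 sprintf("%.17g,%.17g", s$time, s$value)), p)
    paths <- c(paths, p)
  }
  summ <- list(scenario = result$scenario$name,
               observables = lapply(seq_len(nrow(result$summary)), function(k)
                 list(observable = result$summary$observable[k],
                      final = result$summary$final[k],
                      steady = result$summary$steady[k])))
  if (!is.null(reference)) {
    summ$divergence_vs_unperturbed <- lapply(
      names(result$observables), function(nm) {
        d <- compare_trajectories(result$observables[[nm]],
                                  reference$observables[[nm]])
        list(observable = nm, max_abs = d$max_abs, rmse = d$rmse,
             t_max = d$t_max)
      })
  }
  jp <- file.path(dir, paste0(result$scenario$name, "_summary.json"))
  jsonlite::write_json(summ, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, jp))
}
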