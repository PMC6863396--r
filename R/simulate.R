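#' Simulation settings
#'
#' Defaults follow the reference protocol: 10000 s of simulated time reported
#' every 25 s (401 output points) with an LSODA integrator that switches
#' automatically between stiff and non-stiff methods. Tolerances are tight
#' because pools span 0--100 and sensitivity finite-differencing needs
#' headroom.
#'
#' @param t_end end time, seconds.
#' @param output_interval reporting interval, seconds; must divide `t_end`.
#' @param rtol,atol relative / absolute integrator tolerances.
#' @return a list of class `rm_settings`.
#' @export
sim_settings <- function(t_end = 10000, output_interval = 25,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_end > 0, output_interval > 0)
  if (abs(t_end / output_interval - round(t_end / output_interval)) > 1e-9)
    stop("output_interval must divide t_end")
  structure(list(t_end = t_end, output_interval = output_interval,
                 rtol = rtol, atol = atol), class = "rm_settings")
}

#' Timed simulation event
#'
#' An instantaneous action applied at an interior time point: either a rate
#' parameter is reassigned (e.g. a turnover rate raised 1000-fold to mimic a
#' drug) or a species pool is set to a new value (e.g. switching the clamped
#' stiffness input). Integration restarts at the event boundary; simultaneous
#' events apply in list order.
#'
#' @param time event time, seconds (0 < time < t_end).
#' @param action `"set_parameter"` or `"set_species"`.
#' @param name parameter name, or species name for `set_species`.
#' @param value new value.
#' @param pool for `set_species`: `"active"` or `"inactive"`.
#' @return a list of class `rm_event`.
#' @export
sim_event <- function(time, action, name, value, pool = "active") {
  action <- match.arg(action, c("set_parameter", "set_species"))
  pool <- match.arg(pool, c("active", "inactive"))
  structure(list(time = time, action = action, name = name,
                 value = value, pool = pool), class = "rm_event")
}

#' Integrate a compiled model over time
#'
#' Deterministic integration with [deSolve::lsoda()] on a regular output
#' grid. Events split the integration: the state is carried across each
#' boundary, the action applied instantaneously, and the solver restarted.
#' The value recorded at a grid point coinciding with an event time is the
#' pre-event (left-limit) state. A pool
#' undershooting below `-atol * 100` is treated as an integration failure
#' rather than silently clipped.
#'
#' @param model an `rm_model`.
#' @param ics an `rm_state` (defaults to the diagram's default initial
#'   conditions); must satisfy moiety conservation.
#' @param events list of [sim_event()]s.
#' @param settings an `rm_settings`.
#' @return an `rm_trajectory`: list with `time`, `state` (time x pool
#'   matrix), `settings`, `events`, `model`.
#' @export
simulate_model <- function(model, ics = default_initial_conditions(model$wiring),
                           events = list(), settings = sim_settings()) {
  if (!isTRUE(as.logical(check_conservation(ics))))
    stop("initial conditions violate moiety conservation")
  ev_times <- vapply(events, `[[`, numeric(1), "time")
  if (length(events)) {
    if (any(ev_times <= 0 | ev_times >= settings$t_end))
      stop("event times must lie strictly inside (0, t_end)")
    events <- events[order(ev_times)]
    ev_times <- sort(ev_times)
    bad <- vapply(events, function(e) {
      if (e$action == "set_parameter") !(e$name %in% model$parameters$name)
      else !(e$name %in% model$wiring$species$name)
    }, logical(1))
    if (any(bad))
      stop("event references unknown ",
           paste(unique(vapply(events[bad], `[[`, character(1), "name")),
                 collapse = ", "))
  }

  grid <- seq(0, settings$t_end, by = settings$output_interval)
  bounds <- unique(c(0, ev_times, settings$t_end))
  k <- model$parameters$value
  names(k) <- model$parameters$name
  y <- stats::setNames(as.numeric(ics)[match(model$pools, names(ics))],
                       model$pools)
  if (anyNA(y)) stop("initial state does not cover the model's pools")

  deriv_fn <- function(t, y, parms) list(model_derivatives(model, y, parms))
  out <- matrix(NA_real_, nrow = length(grid), ncol = length(model$pools),
                dimnames = list(NULL, model$pools))
  out[1L, ] <- y

  for (s in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1L]
    # apply every event scheduled at this boundary, in list order
    for (e in events[which(abs(ev_times - t0) < 1e-12)]) {
      if (e$action == "set_parameter") k[[e$name]] <- e$value
      else y[[paste0(e$name, if (e$pool == "active") "_a" else "_i")]] <- e$value
    }
    seg_grid <- grid[grid > t0 + 1e-12 & grid <= t1 + 1e-12]
    times <- unique(c(t0, seg_grid, t1))
    sol <- deSolve::lsoda(y, times, deriv_fn, parms = unname(k),
                          rtol = settings$rtol, atol = settings$atol,
                          hmax = t1 - t0, maxsteps = 50000)
    if (attr(sol, "istate")[1L] < 0) {
      y_last <- sol[nrow(sol), -1L]
      dy <- model_derivatives(model, y_last, unname(k))
      scaled <- abs(dy) / pmax(abs(y_last), 1)
      worst <- which.max(scaled)
      stop(sprintf(
        "integration failed near t = %.6g s (worst-scaled derivative: %s, %.3g /s)",
        sol[nrow(sol), 1L], model$pools[worst], scaled[worst]))
    }
    if (min(sol[, -1L]) < -settings$atol * 100)
      stop(sprintf("negative undershoot (%.3g) near t = %.6g s",
                   min(sol[, -1L]),
                   sol[which(sol[, -1L] == min(sol[, -1L]),
                             arr.ind = TRUE)[1L, 1L], 1L]))
    rows <- match(round(seg_grid / settings$output_interval),
                  round(grid / settings$output_interval))
    out[rows, ] <- sol[match(round(seg_grid, 9), round(sol[, 1L], 9)), -1L,
                       drop = FALSE]
    y <- sol[nrow(sol), -1L]
  }
  structure(list(time = grid, state = out, settings = settings,
                 events = events, model = model),
            class = "rm_trajectory")
}

#' @export
print.rm_trajectory <- function(x, ...) {
  cat("rm_trajectory:", length(x$time), "time points (0 to",
      max(x$time), "s),", ncol(x$state), "pools,",
      length(x$events), "event(s)\n")
  invisible(x)
}

#' Extract an observable time series
#'
#' The species' active pool over time, read directly as percent activity on
#' the normalised 0--100 scale (for biophysical entities the active state is
#' the "high" state, e.g. decreased tension or fast rear recoil).
#'
#' @param trajectory an `rm_trajectory`.
#' @param species species name.
#' @return `data.frame` with columns `time` and `value`.
#' @export
observable <- function(trajectory, species) {
  pool <- paste0(species, "_a")
  if (!pool %in% colnames(trajectory$state))
    stop("unknown species: ", species)
  data.frame(time = trajectory$time, value = trajectory$state[, pool])
}

#' Steady-state detection on a trajectory tail
#'
#' A trajectory has converged when, over the trailing `window`, every pool's
#' peak-to-peak excursion is at most `rel_tol` relative to its final value
#' (with a floor of one activity unit on the denominator so near-empty pools
#' are judged on the 0--100 scale rather than their own magnitude).
#'
#' @param trajectory an `rm_trajectory`.
#' @param window trailing window, seconds (must not exceed the span).
#' @param rel_tol relative tolerance.
#' @return list of class `rm_steady`: `converged`, `final_state`,
#'   `worst_change`, `worst_pool`.
#' @export
steady_state <- function(trajectory, window = 1000, rel_tol = 0.01) {
  tt <- trajectory$time
  if (window > max(tt) - min(tt)) stop("window exceeds trajectory span")
  tail_rows <- which(tt >= max(tt) - window)
  xs <- trajectory$state[tail_rows, , drop = FALSE]
  final <- xs[nrow(xs), ]
  span <- apply(xs, 2L, function(col) max(col) - min(col))
  rel <- span / pmax(abs(final), 1)
  worst <- which.max(rel)
  structure(list(converged = all(rel <= rel_tol),
                 final_state = final,
                 worst_change = unname(rel[worst]),
                 worst_pool = colnames(xs)[worst]),
            class = "rm_steady")
}

#' Conservation check along a whole trajectory
#'
#' Every species except the clamped boundary input must keep
#' active + inactive + bound complexes equal to its moiety total at every
#' output point.
#'
#' @param trajectory an `rm_trajectory`.
#' @param tol relative tolerance per species moiety.
#' @return logical; attribute `worst` carries the largest relative deviation
#'   over all species and output times.
#' @export
trajectory_conservation <- function(trajectory, tol = 1e-6) {
  model <- trajectory$model
  diagram <- model$wiring
  ics <- trajectory$state[1L, ]
  worst <- 0
  for (nm in setdiff(diagram$species$name, diagram$input_species)) {
    p <- species_pools(diagram, nm)
    cols <- c(p$active, p$inactive, p$bound)
    tot0 <- sum(ics[cols])
    dev <- max(abs(rowSums(trajectory$state[, cols, drop = FALSE]) - tot0)) /
      max(tot0, 1)
    worst <- max(worst, dev)
  }
  structure(worst <= tol, worst = worst)
}

#' Write / read a trajectory as CSV
#'
#' Plain comma-separated text: first column `time_s`, one column per pool
#' with canonical pool names in the header, values at 17 significant digits
#' so the round trip is lossless at double precision.
#'
#' @param trajectory an `rm_trajectory`.
#' @param path file path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns a `data.frame` with `time_s` first.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  m <- cbind(time_s = trajectory$time, trajectory$state)
  lines <- c(paste(colnames(m), collapse = ","),
             apply(m, 1L, function(r)
               paste(sprintf("%.17g", r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param path file path.
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
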