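# Damped Newton polish of a near-steady state. The Jacobian is singular
# (moiety conservation, clamped input), so the step is the minimum-norm
# least-squares solution, which stays on the conservation manifold.
newton_polish <- function(model, y, k = model$parameters$value,
                          tol = 1e-11, max_iter = 50) {
  f <- model_derivatives(model, y, k)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) <= tol) return(list(state = y, converged = TRUE))
    n <- length(y)
    J <- matrix(0, n, n)
    h <- pmax(abs(y), 1) * 1e-7
    for (j in seq_len(n)) {
      yj <- y; yj[j] <- yj[j] + h[j]
      J[, j] <- (model_derivatives(model, yj, k) - f) / h[j]
    }
    sv <- svd(J)
    keep <- sv$d > max(sv$d) * 1e-10
    step <- -sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], f)) / sv$d[keep])
    lambda <- 1
    repeat {
      y_new <- y + lambda * as.numeric(step)
      f_new <- model_derivatives(model, y_new, k)
      if (max(abs(f_new)) < max(abs(f)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (max(abs(f_new)) >= max(abs(f))) return(list(state = y, converged = FALSE))
    y <- y_new; f <- f_new
  }
  list(state = y, converged = max(abs(f)) <= tol)
}

#' Steady state of the unperturbed scenario
#'
#' Integrates the unperturbed scenario (clamped input at 100, default
#' initial conditions) over an initial horizon, then polishes the endpoint
#' to machine-accurate steadiness with a damped Newton iteration on the
#' mass-action derivative contract; if the polish fails the horizon is
#' doubled up to a cap.
#'
#' @param model an `rm_model`.
#' @param rel_tol trailing-window convergence tolerance used when Newton
#'   polishing is unavailable.
#' @param t_max horizon cap, seconds.
#' @return list: `state` (named vector), `t_end`, `converged`.
#' @keywords internal
unperturbed_steady_state <- function(model, rel_tol = 1e-6, t_max = 320000) {
  ics <- default_initial_conditions(model$wiring)
  t_end <- 20000
  repeat {
    traj <- simulate_model(model, ics,
                           settings = sim_settings(t_end, t_end / 400))
    end_state <- traj$state[nrow(traj$state), ]
    pol <- newton_polish(model, end_state)
    if (pol$converged && min(pol$state) > -1e-8)
      return(list(state = pol$state, t_end = t_end, converged = TRUE))
    ss <- steady_state(traj, window = max(1000, t_end / 20), rel_tol = rel_tol)
    if (ss$converged)
      return(list(state = ss$final_state, t_end = t_end, converged = TRUE))
    if (t_end >= t_max)
      return(list(state = ss$final_state, t_end = t_end, converged = FALSE,
                  worst = ss$worst_change))
    t_end <- t_end * 2
  }
}

#' Scaled parameter sensitivities of steady-state rear retraction
#'
#' For each rate constant k the scaled (dimensionless) sensitivity
#' S = (k/R) dR/dk is estimated by central differences at relative step
#' `delta`, where R is the steady-state active rear-retraction level of the
#' unperturbed scenario. Because uniformly rescaling all mass-action rates
#' only rescales time, steady states are invariant under such a rescaling
#' and the sensitivities sum to zero; the reported sum is a global accuracy
#' check on the analysis.
#'
#' @param model an `rm_model`.
#' @param delta relative finite-difference step (default 0.01).
#' @param target observable species (default `"RearRetraction"`).
#' @param rel_tol steady-state tolerance.
#' @return an `rm_sensitivity` object: `data.frame` `report` with columns
#'   `parameter`, `class`, `value`, `S`; plus `sum_S`, `target`, `delta`,
#'   `R0`.
#' @export
scaled_sensitivities <- function(model, delta = 0.01,
                                 target = "RearRetraction", rel_tol = 1e-6) {
  base <- unperturbed_steady_state(model, rel_tol = rel_tol)
  if (!base$converged)
    stop(sprintf(
      "unperturbed scenario did not reach steady state (worst change %.3g)",
      base$worst))
  pool <- paste0(target, "_a")
  R0 <- base$state[[pool]]
  if (R0 <= 0)
    stop("steady-state target is zero; scaled sensitivity undefined")
  t_end <- base$t_end
  eval_R <- function(values) {
    m2 <- model
    m2$parameters$value <- values
    traj <- simulate_model(m2, default_initial_conditions(model$wiring),
                           settings = sim_settings(t_end, t_end / 400))
    end_state <- traj$state[nrow(traj$state), ]
    pol <- newton_polish(m2, end_state)
    if (pol$converged) pol$state[[pool]] else end_state[[pool]]
  }
  k0 <- model$parameters$value
  S <- vapply(seq_along(k0), function(i) {
    up <- k0; up[i] <- k0[i] * (1 + delta)
    dn <- k0; dn[i] <- k0[i] * (1 - delta)
    (eval_R(up) - eval_R(dn)) / (2 * delta * R0)
  }, numeric(1))
  report <- data.frame(parameter = model$parameters$name,
                       class = model$parameters$class,
                       value = k0, S = S, stringsAsFactors = FALSE)
  structure(list(report = report, sum_S = sum(S), target = target,
                 delta = delta, R0 = R0),
            class = "rm_sensitivity")
}

#' @export
print.rm_sensitivity <- function(x, ...) {
  cat(sprintf("scaled sensitivities of steady-state %s (R = %.3f, delta = %g)\n",
              x$target, x$R0, x$delta))
  cat(sprintf("  sum over %d parameters: %.3e\n", nrow(x$report), x$sum_S))
  top <- x$report[order(-abs(x$report$S)), ][1:min(5, nrow(x$report)), ]
  for (k in seq_len(nrow(top)))
    cat(sprintf("  %-28s S = %+.4f\n", top$parameter[k], top$S[k]))
  invisible(x)
}

#' Rank parameters by sensitivity magnitude
#'
#' @param report an `rm_sensitivity`.
#' @param top_n number of parameters to return (truncated to the available
#'   count).
#' @return character vector of parameter names ordered by decreasing |S|,
#'   ties broken by canonical (compiled) parameter order.
#' @export
rank_critical <- function(report, top_n = 5) {
  df <- report$report
  ord <- order(-abs(df$S), seq_len(nrow(df)))
  df$parameter[ord][seq_len(min(max(top_n, 0), nrow(df)))]
}

#' Halve/double robustness sweep
#'
#' Each listed parameter is multiplied in turn by each factor (default 0.5
#' and 2), the unperturbed and no-input scenarios are re-run, and the
#' behaviour is re-classified. A robust parameterisation keeps the
#' "responsive with input / quiescent without" classification under every
#' such perturbation.
#'
#' @param model an `rm_model`.
#' @param parameters parameter names to sweep (e.g. from [rank_critical()]).
#' @param factors multiplicative factors.
#' @param thresholds a [behavior_thresholds()].
#' @param settings an `rm_settings`.
#' @return an `rm_sweep`: `data.frame` with `parameter`, `factor`,
#'   `final_with_input`, `final_without`, `class`, `changed`; plus the
#'   baseline classification.
#' @export
robustness_sweep <- function(model, parameters, factors = c(0.5, 2.0),
                             thresholds = behavior_thresholds(),
                             settings = sim_settings()) {
  unknown <- setdiff(parameters, model$parameters$name)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  classify <- function(m) {
    with_in <- run_scenario("unperturbed", m, settings)
    without <- run_scenario("no_input", m, settings)
    classify_behavior(with_in, without, thresholds)
  }
  baseline <- classify(model)
  rows <- list()
  for (p in parameters) for (f in factors) {
    m2 <- model
    i <- match(p, m2$parameters$name)
    m2$parameters$value[i] <- m2$parameters$value[i] * f
    cls <- tryCatch(classify(m2), error = function(e) "integration_failure")
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = p, factor = f, class = cls,
      changed = !identical(cls, baseline), stringsAsFactors = FALSE)
  }
  structure(list(baseline = baseline, sweep = do.call(rbind, rows),
                 factors = factors),
            class = "rm_sweep")
}

#' @export
print.rm_sweep <- function(x, ...) {
  cat("robustness sweep; baseline class:", x$baseline, "\n")
  n_changed <- sum(x$sweep$changed)
  cat(sprintf("  %d/%d perturbations change the classification\n",
              n_changed, nrow(x$sweep)))
  if (n_changed)
    print(x$sweep[x$sweep$changed, ])
  invisible(x)
}

#' Export a sensitivity report
#'
#' @param report an `rm_sensitivity`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return written paths, invisibly.
#' @export
export_sensitivity <- function(report, csv_path = NULL, json_path = NULL) {
  out <- character()
  if (!is.null(csv_path)) {
    df <- report$report
    lines <- c("parameter,class,value,S",
               sprintf("%s,%s,%.17g,%.17g", df$parameter, df$class,
                       df$value, df$S))
    writeLines(lines, csv_path)
    out <- c(out, csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(target = report$target, delta = report$delta, R0 = report$R0,
           sum_S = report$sum_S,
           sensitivities = report$report),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows",
      pretty = TRUE)
    out <- c(out, json_path)
  }
  invisible(out)
}
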