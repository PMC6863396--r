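#' Sampler configuration for parameter-profile ensembles
#'
#' Emulates the model's parameter uncertainty: rates live on the
#' order-of-magnitude grid 1e-n and protein-protein steps are drawn from a
#' faster (lower-n) window than biophysical steps, with the turnover rates
#' that the perturbation events scale anchored at their 0.01 baseline.
#'
#' @param seed integer seed; the same seed always reproduces the same
#'   profiles.
#' @param n_profiles number of profiles to draw.
#' @param exponent_ranges named list of integer exponent ranges per class.
#' @param anchors named numeric vector of parameters fixed at given values.
#' @return a list of class `rm_sampler_config`.
#' @export
sampler_config <- function(seed, n_profiles,
                           exponent_ranges = list(protein = 1:3,
                                                  biophysical = 2:4,
                                                  turnover = 2:3),
                           anchors = c(kt_MembraneTension = 0.01,
                                       kt_Actin = 0.01,
                                       kt_ROCK1 = 0.01,
                                       kt_PKN2 = 0.01)) {
  stopifnot(length(seed) == 1L, n_profiles >= 1,
            all(lengths(exponent_ranges) > 0))
  expo <- -log10(anchors)
  if (any(abs(expo - round(expo)) > 1e-9))
    stop("anchored values must lie on the 1e-n grid")
  structure(list(seed = as.integer(seed), n_profiles = as.integer(n_profiles),
                 exponent_ranges = exponent_ranges, anchors = anchors),
            class = "rm_sampler_config")
}

#' Sample parameter profiles on the order-of-magnitude grid
#'
#' Every non-anchored forward rate is drawn uniformly over its class's
#' exponent range; every reverse rate is set to 10% of its sampled forward;
#' anchored parameters keep their fixed values. Deterministic given the
#' config seed (the global RNG state is restored on exit).
#'
#' @param config an [sampler_config()].
#' @param diagram wiring diagram whose parameter roster is sampled.
#' @return list of parameter profile `data.frame`s (see
#'   [default_parameters()] for the format).
#' @export
sample_parameter_profiles <- function(config, diagram = canonical_wiring()) {
  template <- default_parameters(diagram)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  fwd_idx <- which(!template$is_reverse &
                     !(template$name %in% names(config$anchors)))
  lapply(seq_len(config$n_profiles), function(i) {
    p <- template
    for (j in fwd_idx) {
      rng <- config$exponent_ranges[[p$class[j]]]
      p$value[j] <- 10^(-rng[sample.int(length(rng), 1L)])
    }
    for (nm in names(config$anchors))
      p$value[p$name == nm] <- config$anchors[[nm]]
    rev <- which(p$is_reverse)
    p$value[rev] <- 0.1 * p$value[match(p$paired_forward[rev], p$name)]
    p
  })
}

#' Behaviour classification thresholds
#'
#' Operationalise the qualitative readout of the unperturbed/no-input pair:
#' "high steady state" means a final rear-retraction activity of at least
#' `responsive_min`, "negligible" means at most `quiescent_max`.
#'
#' @param responsive_min activity units (default 50).
#' @param quiescent_max activity units (default 5).
#' @param window steady-state window, seconds.
#' @param rel_tol steady-state relative tolerance.
#' @return a list of class `rm_thresholds`.
#' @export
behavior_thresholds <- function(responsive_min = 50, quiescent_max = 5,
                                window = 1000, rel_tol = 0.01) {
  stopifnot(quiescent_max < responsive_min)
  structure(list(responsive_min = responsive_min,
                 quiescent_max = quiescent_max,
                 window = window, rel_tol = rel_tol),
            class = "rm_thresholds")
}

#' Classify model behaviour from the input/no-input scenario pair
#'
#' `"faithful"` means the model is responsive with the stiffness input
#' (final rear retraction at or above `responsive_min`, converged) and
#' quiescent without it (final at or below `quiescent_max`). Otherwise the
#' first failing clause names the class: `"non_convergent"`,
#' `"non_responsive"` or `"constitutive"`.
#'
#' @param result_with_input,result_without `rm_scenario_result`s for the
#'   unperturbed and no-input scenarios.
#' @param thresholds a [behavior_thresholds()].
#' @return character class label.
#' @export
classify_behavior <- function(result_with_input, result_without,
                              thresholds = behavior_thresholds()) {
  ss <- steady_state(result_with_input$trajectory,
                     window = thresholds$window, rel_tol = thresholds$rel_tol)
  fin_with <- result_with_input$summary$final[
    result_with_input$summary$observable == "RearRetraction"]
  fin_without <- result_without$summary$final[
    result_without$summary$observable == "RearRetraction"]
  if (!ss$converged) return("non_convergent")
  if (fin_with < thresholds$responsive_min) return("non_responsive")
  if (fin_without > thresholds$quiescent_max) return("constitutive")
  "faithful"
}

#' Ensemble robustness summary
#'
#' Runs the unperturbed and no-input scenarios for each profile, classifies
#' each, and reports per-class counts and the faithful fraction.
#' Integration failures are recorded per profile, never fatal.
#'
#' @param profiles list of parameter profiles (see
#'   [sample_parameter_profiles()]).
#' @param thresholds a [behavior_thresholds()].
#' @param diagram wiring diagram.
#' @param settings an `rm_settings`.
#' @param seed seed echoed into the report (provenance only).
#' @return an `rm_ensemble`: `data.frame` `classes` (profile, class),
#'   `counts`, `faithful_fraction`, `seed`.
#' @export
ensemble_summary <- function(profiles, thresholds = behavior_thresholds(),
                             diagram = canonical_wiring(),
                             settings = sim_settings(), seed = NA_integer_) {
  stopifnot(length(profiles) >= 1)
  cls <- vapply(seq_along(profiles), function(i) {
    tryCatch({
      m <- compile_model(diagram, profiles[[i]])
      classify_behavior(run_scenario("unperturbed", m, settings),
                        run_scenario("no_input", m, settings),
                        thresholds)
    }, error = function(e) "integration_failure")
  }, character(1))
  counts <- table(factor(cls, levels = c("faithful", "non_responsive",
                                         "constitutive", "non_convergent",
                                         "integration_failure")))
  structure(list(classes = data.frame(profile = seq_along(profiles),
                                      class = cls, stringsAsFactors = FALSE),
                 counts = counts,
                 faithful_fraction = mean(cls == "faithful"),
                 seed = seed),
            class = "rm_ensemble")
}

#' @export
print.rm_ensemble <- function(x, ...) {
  cat(sprintf("ensemble of %d profiles (seed %s): faithful fraction %.3f\n",
              nrow(x$classes), x$seed, x$faithful_fraction))
  print(x$counts)
  invisible(x)
}
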