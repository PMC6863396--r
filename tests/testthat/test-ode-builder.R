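w <- canonical_wiring()

test_that("edge expansion follows the two-step / one-step contracts", {
  # reversible two-step activation: bind/unbind/convert/reverse-convert
  e <- w$edges[w$edges$source == "Ect2" & w$edges$target == "RhoA", ]
  rx <- expand_edge(e, w$species)
  expect_length(rx, 4L)
  kinds <- vapply(rx, `[[`, character(1), "kind")
  expect_equal(sort(kinds), c("binding", "binding", "conversion", "conversion"))
  # bind consumes the inactive target, convert releases the active target
  expect_true("RhoA_i" %in% names(rx[[1]]$reactants))
  expect_true("RhoA_a" %in% names(rx[[3]]$products))
  expect_true("cx_Ect2_RhoA" %in% names(rx[[1]]$products))

  # reversible two-step inhibition consumes the active target
  e2 <- w$edges[w$edges$source == "LIMK" & w$edges$target == "Cofilin", ]
  rx2 <- expand_edge(e2, w$species)
  expect_length(rx2, 4L)
  expect_true("Cofilin_a" %in% names(rx2[[1]]$reactants))
  expect_true("Cofilin_i" %in% names(rx2[[3]]$products))

  # irreversible one-step: exactly one reaction, catalyst regenerated
  e3 <- w$edges[w$edges$source == "MembraneTension" & w$edges$target == "Caveolae", ]
  rx3 <- expand_edge(e3, w$species)
  expect_length(rx3, 1L)
  expect_true("MembraneTension_a" %in% names(rx3[[1]]$reactants))
  expect_true("MembraneTension_a" %in% names(rx3[[1]]$products))

  # mechanism inconsistent with categories is rejected
  bad <- e3
  bad$mechanism <- "two_step"
  expect_error(expand_edge(bad, w$species), "one-step")
})

test_that("turnover covers all species except pMLC and the clamped input", {
  rx <- add_turnover(w$species)
  expect_length(rx, 17L)
  targets <- vapply(rx, function(r) names(r$reactants), character(1))
  expect_false("pMLC_a" %in% targets)
  expect_false("PolarizedSubstrateStiffness_a" %in% targets)
  # a single unclamped protein gets exactly one turnover reaction
  one <- species_def("Solo", "protein")
  expect_length(add_turnover(one), 1L)
  # pMLC alone yields none
  pm <- w$species[w$species$name == "pMLC", ]
  expect_length(add_turnover(pm), 0L)
})

test_that("compiled canonical model has the expected inventory", {
  m <- compile_model(w)
  # pools: active+inactive per species plus one complex per two-step edge
  n_two <- sum(w$edges$mechanism == "two_step")
  expect_equal(length(m$pools), 2L * nrow(w$species) + n_two)
  # reactions: 4 per reversible two-step edge, 1 or 2 per one-step edge,
  # 17 turnover (regression-fixed totals for the canonical diagram)
  n_one_rev <- sum(w$edges$mechanism == "one_step" & w$edges$reversible)
  n_one <- sum(w$edges$mechanism == "one_step")
  expect_length(m$reactions, 4L * n_two + n_one + n_one_rev + 17L)
  expect_length(m$reactions, 100L)
  # every reaction's rate constant resolves; every parameter on the grid
  expect_true(all(vapply(m$reactions, `[[`, character(1), "rate_constant")
                  %in% m$parameters$name))
  expo <- -log10(m$parameters$value)
  expect_true(all(abs(expo - round(expo)) < 1e-9))
})

test_that("moiety conservation is structural in every reaction", {
  m <- compile_model(w)
  for (nm in w$species$name) {
    p <- rearmech:::species_pools(m$wiring, nm)
    cols <- c(p$active, p$inactive, p$bound)
    # summed stoichiometry of the species' pools is zero in every reaction
    expect_true(all(abs(colSums(m$stoich[cols, , drop = FALSE])) < 1e-12),
                label = paste("conservation for", nm))
  }
})

test_that("derivative contract matches brute-force flux accumulation", {
  m <- compile_model(w)
  set.seed(11)
  for (rep in 1:5) {
    y <- stats::setNames(runif(length(m$pools), 0, 100), m$pools)
    expect_equal(unname(model_derivatives(m, y)),
                 unname(rearmech:::derivatives_by_enumeration(m, y)),
                 tolerance = 1e-12)
  }
  # zero-flux case: at default ICs rear retraction has no active driver
  ics <- default_initial_conditions(w)
  d <- model_derivatives(m, ics[m$pools])
  expect_equal(unname(d[match("RearRetraction_a", m$pools)]), 0)
  # clamped input never moves
  expect_equal(unname(d[match("PolarizedSubstrateStiffness_a", m$pools)]), 0)
})

test_that("compilation is deterministic", {
  m1 <- compile_model(w)
  m2 <- compile_model(canonical_wiring())
  expect_identical(vapply(m1$reactions, `[[`, character(1), "rate_constant"),
                   vapply(m2$reactions, `[[`, character(1), "rate_constant"))
  expect_identical(m1$pools, m2$pools)
  expect_identical(m1$stoich, m2$stoich)
})

test_that("parameter constraints catch grid, reversibility and class violations", {
  p <- default_parameters(w)
  expect_true(check_parameter_constraints(p)$valid)

  p2 <- p
  p2$value[1] <- 0.05  # off the 1e-n grid
  rep2 <- check_parameter_constraints(p2)
  expect_true("grid" %in% rep2$violations$rule)

  p3 <- p
  fwd <- which(!p3$is_reverse)[1]
  rev <- which(p3$paired_forward == p3$name[fwd])[1]
  p3$value[rev] <- 0.2 * p3$value[fwd]
  # keep it on the grid so only the reversibility rule fires
  p3$value[rev] <- 10^floor(log10(p3$value[rev]))
  if (p3$value[rev] <= 0.1 * p3$value[fwd]) p3$value[rev] <- p3$value[fwd]
  rep3 <- check_parameter_constraints(p3)
  expect_true("reversibility" %in% rep3$violations$rule)

  p4 <- p
  p4$value[p4$name == "kt_MembraneTension"] <- 1e-1  # above turnover window
  expect_true("class_ordering" %in%
                check_parameter_constraints(p4)$violations$rule)
  # compile_model refuses profiles that violate the constraints
  expect_error(compile_model(w, p4), "constraint")
})
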