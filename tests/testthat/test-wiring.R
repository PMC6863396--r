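test_that("canonical wiring has the expected roster structure", {
  w <- canonical_wiring()
  expect_equal(nrow(w$species), 19L)
  expect_equal(sum(w$species$category == "protein"), 12L)
  expect_equal(sum(w$species$category == "complex"), 1L)
  expect_equal(sum(w$species$is_clamped_input), 1L)
  expect_equal(w$input_species, "PolarizedSubstrateStiffness")
  # exactly one turnover-exempt species besides the clamped input
  exempt <- w$species$name[!w$species$has_turnover & !w$species$is_clamped_input]
  expect_equal(exempt, "pMLC")
  # tension -> caveolae is present and irreversible
  e <- w$edges[w$edges$source == "MembraneTension" &
                 w$edges$target == "Caveolae", ]
  expect_equal(nrow(e), 1L)
  expect_false(e$reversible)
  expect_equal(e$mechanism, "one_step")
  # both inputs of contractility are irreversible
  amc <- w$edges[w$edges$target == "ActoMyosinContractility", ]
  expect_true(all(!amc$reversible))
})

test_that("canonical wiring validates clean and edge rules are enforced", {
  w <- canonical_wiring()
  rep <- validate_wiring(w)
  expect_true(rep$valid)
  expect_equal(nrow(rep$violations), 0L)

  # unknown endpoint
  w2 <- w
  w2$edges$target[1] <- "Ghost"
  rep2 <- validate_wiring(w2)
  expect_false(rep2$valid)
  expect_true("unknown_endpoint" %in% rep2$violations$rule)

  # protein-protein edge wrongly declared one-step (target not pMLC)
  w3 <- w
  k <- which(w3$edges$source == "Ect2" & w3$edges$target == "RhoA")
  w3$edges$mechanism[k] <- "one_step"
  rep3 <- validate_wiring(w3)
  expect_true("rule_iv" %in% rep3$violations$rule)

  # biophysical edge wrongly declared two-step
  w4 <- w
  k <- which(w4$edges$source == "PolarizedSubstrateStiffness")
  w4$edges$mechanism[k] <- "two_step"
  expect_true("rule_v" %in% validate_wiring(w4)$violations$rule)

  # designated irreversible edge marked reversible
  w5 <- w
  k <- which(w5$edges$source == "MembraneTension" & w5$edges$target == "Caveolae")
  w5$edges$reversible[k] <- TRUE
  expect_true("rule_vi" %in% validate_wiring(w5)$violations$rule)
})

test_that("default initial conditions follow the stated protocol", {
  w <- canonical_wiring()
  s <- default_initial_conditions(w)
  expect_equal(unname(s[["PolarizedSubstrateStiffness_a"]]), 100)
  expect_equal(unname(s[["Src_a"]]), 50)
  expect_equal(unname(s[["Src_i"]]), 50)  # conservation-forced remainder
  expect_equal(unname(s[["Cofilin_a"]]), 100)
  expect_equal(unname(s[["MLCP_a"]]), 100)
  expect_equal(unname(s[["RhoA_a"]]), 0)
  expect_equal(unname(s[["RearRetraction_a"]]), 0)
  expect_true(all(s[grep("^cx_", names(s))] == 0))
  expect_true(as.logical(check_conservation(s)))
})

test_that("invalid diagrams are rejected by the state constructor", {
  w <- canonical_wiring()
  w$species$initial_active[w$species$name == "Src"] <- 150
  expect_error(default_initial_conditions(w), "moiety_bounds")
})

test_that("knockdown rescales both pools and composes multiplicatively", {
  w <- canonical_wiring()
  s <- default_initial_conditions(w)
  kd <- apply_knockdown(s, "RhoA", 0.12)
  expect_equal(unname(kd[["RhoA_a"]] + kd[["RhoA_i"]]), 12)
  expect_true(as.logical(check_conservation(kd)))
  # identity at fraction 1
  expect_equal(as.numeric(apply_knockdown(s, "RhoA", 1)), as.numeric(s))
  # full knockdown zeroes the pools, conservation still holds
  z <- apply_knockdown(s, "Caveolae", 0)
  expect_equal(unname(z[["Caveolae_a"]] + z[["Caveolae_i"]]), 0)
  expect_true(as.logical(check_conservation(z)))
  # multiplicative composition
  ab <- apply_knockdown(apply_knockdown(s, "Src", 0.5), "Src", 0.4)
  expect_equal(as.numeric(ab), as.numeric(apply_knockdown(s, "Src", 0.2)))
  expect_error(apply_knockdown(s, "NotASpecies", 0.5), "unknown species")
})
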