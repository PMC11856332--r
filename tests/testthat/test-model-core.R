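test_that("total_population sums all 10 compartments", {
  expect_equal(total_population(setNames(rep(100, 10), names(state_vector()))), 1000)
  expect_equal(total_population(state_vector()), 0)
  expect_equal(total_population(state_vector(Sr = 9999.5)), 9999.5)
})

test_that("state validation rejects malformed states", {
  expect_error(state_vector(Sr = -1), class = "sirsmig_invalid_state")
  expect_error(total_population(c(Sr = 1)), class = "sirsmig_invalid_state")
  expect_error(total_population(state_vector() * NA), class = "sirsmig_invalid_state")
})

test_that("shared-habitat derivatives match hand evaluation", {
  p <- model_params()
  expect_equal(rhs_shared_habitat(state_vector(), p),
               setNames(rep(0, 10), names(state_vector())))
  # lone susceptible residents: births minus natural mortality
  d1 <- rhs_shared_habitat(state_vector(Sr = 100), p)
  expect_equal(unname(d1["Sr"]), 2 * 100 * (1 - 0.01) - 0.14 * 100)
  expect_equal(unname(d1["Sr"]), 184)
  expect_true(all(d1[names(d1) != "Sr"] == 0))
  # lone resistant residents losing immunity at mu = 0.5
  d2 <- rhs_shared_habitat(state_vector(Rr = 100), model_params(mu = 0.5))
  expect_equal(unname(d2["Sr"]), 0.5 * 100 + 2 * 100 * (1 - 0.01))
  expect_equal(unname(d2["Sr"]), 248)
  expect_equal(unname(d2["Rr"]), -64)
})

test_that("separate-habitat derivatives match hand evaluation", {
  p <- model_params()
  expect_equal(rhs_separate_habitats(state_vector(), p),
               setNames(rep(0, 10), names(state_vector())))
  # no reproduction while apart: susceptibles only decay
  d1 <- rhs_separate_habitats(state_vector(Sr = 100), p)
  expect_equal(unname(d1["Sr"]), -14)
  # infected migrants recover at the Habitat 2 rate nu2
  d2 <- rhs_separate_habitats(state_vector(Im1 = 100),
                              model_params(nu1 = 0.14)) # nu2 = 0.26
  expect_equal(unname(d2["Im1"]), -(0.26 + 0.14 + 0.01) * 100)
  expect_equal(unname(d2["Rm"]), 26)
  expect_equal(unname(d2["Sm"]), 0)
})

test_that("both derivative fields agree with an independent transcription at random states", {
  set.seed(42)
  for (k in 1:100) {
    p <- random_params()
    s <- random_state()
    expect_equal(unname(rhs_shared_habitat(s, p)), oracle_rhs_shared(unname(s), p),
                 tolerance = 1e-12)
    expect_equal(unname(rhs_separate_habitats(s, p)),
                 oracle_rhs_separate(unname(s), p), tolerance = 1e-12)
  }
})

test_that("disease-free subspace is invariant in both seasons", {
  set.seed(7)
  for (k in 1:20) {
    p <- random_params()
    s <- state_vector(Sr = runif(1, 0, 1000), Sm = runif(1, 0, 1000))
    for (f in list(rhs_shared_habitat, rhs_separate_habitats)) {
      d <- f(s, p)
      expect_true(all(d[c("Ir1", "Ir2", "Ir3", "Rr", "Im1", "Im2", "Im3", "Rm")] == 0))
    }
  }
})

test_that("migration pulse scales only migrant classes, never upward", {
  p <- model_params(delta_S = 0.001, delta_I = 0.004, delta_R = 0.001)
  s <- setNames(rep(100, 10), names(state_vector()))
  out <- apply_migration_pulse(s, p)
  expect_equal(unname(out["Sm"]), 99.9)
  expect_equal(unname(out[c("Im1", "Im2", "Im3")]), rep(99.6, 3))
  expect_equal(unname(out["Rm"]), 99.9)
  expect_equal(out[c("Sr", "Ir1", "Ir2", "Ir3", "Rr")],
               s[c("Sr", "Ir1", "Ir2", "Ir3", "Rr")])
  # delta_I = 0.004 on 200 infected migrants
  out2 <- apply_migration_pulse(state_vector(Im1 = 200), p)
  expect_equal(unname(out2["Im1"]), 199.2)
  # zero mortality fractions: identity
  expect_equal(apply_migration_pulse(s, model_params(delta_S = 0, delta_I = 0,
                                                     delta_R = 0)), s)
  # property: never increases any component, residents untouched
  set.seed(11)
  for (k in 1:20) {
    pr <- random_params()
    sr <- random_state()
    o <- apply_migration_pulse(sr, pr)
    expect_true(all(o <= sr + 1e-15))
    expect_equal(o[c("Sr", "Ir1", "Ir2", "Ir3", "Rr")],
                 sr[c("Sr", "Ir1", "Ir2", "Ir3", "Rr")])
  }
})
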