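test_that("parameter constructor enforces its contracts", {
  expect_s3_class(kinetic_params(), "kinetic_params")
  expect_error(kinetic_params(Y_H = 1.2), "Y_H")
  expect_error(kinetic_params(mu_H_hat = -1), "positive|> 0")
  expect_error(kinetic_params(f_S = 0.6, f_X = 0.5), "f_S")
})

test_that("stoichiometric matrix carries the documented coefficients", {
  p <- kinetic_params(Y_H = 0.5, f_S = 0.05, f_X = 0.2)
  m <- build_petersen(p, "masm")
  expect_identical(dim(m$stoich), c(6L, 12L))
  # growth at Y_H = 0.5: -1/Y on substrate, -(1-Y)/Y on oxygen
  expect_equal(m$stoich["growth", "S_S"], -2)
  expect_equal(m$stoich["growth", "S_O"], -1)
  expect_equal(m$stoich["growth", "X_H"], 1)
  # decay residue partitioning
  expect_equal(m$stoich["decay", "X_P"], p$f_X)
  expect_equal(m$stoich["decay", "S_P"], p$f_S)
  expect_equal(m$stoich["decay", "S_O"], -(1 - p$f_S - p$f_X))
  # membrane routing: settleable COD hydrolyses to the captured soluble pool
  expect_equal(m$stoich["hydrolysis_X_SS", "X_SS"], -1)
  expect_equal(m$stoich["hydrolysis_X_SS", "S_HC"], 1)
  # ASM1-type routing: settleable COD hydrolyses straight to S_S
  m2 <- build_petersen(p, "asm1_mod")
  expect_equal(m2$stoich["hydrolysis_X_SS", "S_S"], 1)
  expect_equal(sum(abs(m2$stoich["hydrolysis_S_HC", ])), 0)
  expect_error(build_petersen(p, "nonsense"))
})

test_that("COD continuity holds per process row for both variants", {
  for (variant in c("masm", "asm1_mod")) {
    m <- build_petersen(kinetic_params(), variant)
    expect_lt(max(abs(continuity_defect(m))), 1e-12)
  }
  # injected fault is reported at its magnitude
  m <- build_petersen(kinetic_params(), "masm")
  m$stoich["decay", "X_P"] <- m$stoich["decay", "X_P"] + 0.1
  expect_equal(unname(continuity_defect(m)["decay"]), 0.1)
})

test_that("process rates match hand-evaluated kinetics", {
  p <- kinetic_params()
  m <- build_petersen(p, "masm")
  # Monod growth at the half-saturation point
  s <- state_vector(S_S = 15, X_H = 1000)
  expect_equal(unname(process_rates(s, p, m)["growth"]), 0.5 * 3.6 * 1000)
  # surface-saturation hydrolysis, hand evaluation
  s <- state_vector(S_H = 100, X_H = 1000)
  expect_equal(unname(process_rates(s, p, m)["hydrolysis_S_H"]),
               2.45 * (0.1 / 0.19) * 1000, tolerance = 1e-12)
  # biomass-free limit: every rate vanishes
  s <- state_vector(S_S = 500, S_H = 500, S_HC = 500, X_S = 500, X_SS = 500)
  expect_true(all(process_rates(s, p, m) == 0))
  neg <- unclass(state_vector(X_H = 100)); neg["S_S"] <- -5
  expect_error(process_rates(neg, p, m), "non-negative")
})

test_that("rates are monotone in their substrate and in biomass", {
  p <- kinetic_params()
  m <- build_petersen(p, "masm")
  subst <- c(growth = "S_S", hydrolysis_S_H = "S_H", hydrolysis_S_HC = "S_HC",
             hydrolysis_X_S = "X_S", hydrolysis_X_SS = "X_SS", decay = "X_H")
  grid <- c(0, 1, 10, 100, 1000)
  for (proc in names(subst)) {
    r_sub <- vapply(grid, function(v) {
      args <- stats::setNames(list(v, 800), c(subst[proc], "X_H"))
      process_rates(do.call(state_vector, args), p, m)[[proc]]
    }, 0)
    expect_true(all(diff(r_sub) >= 0), info = paste(proc, "in substrate"))
    r_bio <- vapply(grid, function(v) {
      args <- stats::setNames(list(200, v), c(subst[proc], "X_H"))
      if (proc == "decay") args <- list(X_H = v)
      process_rates(do.call(state_vector, args), p, m)[[proc]]
    }, 0)
    expect_true(all(diff(r_bio) >= 0), info = paste(proc, "in X_H"))
  }
})

test_that("growth and decay rates are identical across variants", {
  p <- kinetic_params()
  m1 <- build_petersen(p, "masm")
  m2 <- build_petersen(p, "asm1_mod")
  set.seed(41)
  for (i in 1:20) {
    s <- random_state()
    r1 <- process_rates(s, p, m1)
    r2 <- process_rates(s, p, m2)
    expect_equal(r1[c("growth", "decay")], r2[c("growth", "decay")])
  }
})

test_that("net reaction derivatives conserve total COD", {
  p <- kinetic_params()
  codc <- setdiff(masm_components(), "S_O")
  for (variant in c("masm", "asm1_mod")) {
    m <- build_petersen(p, variant)
    expect_equal(unname(reaction_derivatives(state_vector(), p, m)),
                 rep(0, 12))
    set.seed(7)
    for (i in 1:1000) {
      s <- random_state()
      d <- reaction_derivatives(s, p, m)
      our <- oxygen_uptake_rate(s, p, m)
      # COD destroyed by reaction must equal oxygen consumed
      expect_equal(sum(d[codc]), -our, tolerance = 1e-9)
    }
  }
})

test_that("single-process activation routes settleable COD through S_HC", {
  p <- kinetic_params()
  m <- build_petersen(p, "masm")
  s <- state_vector(X_SS = 100, X_H = 500)
  d <- reaction_derivatives(s, p, m)
  r <- process_rates(s, p, m)
  expect_gt(r[["hydrolysis_X_SS"]], 0)
  expect_equal(d[["S_HC"]], r[["hydrolysis_X_SS"]])
  expect_equal(d[["X_SS"]], -r[["hydrolysis_X_SS"]])
  expect_equal(r[["growth"]], 0)              # no growth without S_S
  expect_equal(d[["S_S"]], 0)
  expect_equal(d[["X_H"]], -r[["decay"]])     # only decay touches biomass
})

test_that("oxygen uptake combines growth and endogenous respiration", {
  p <- kinetic_params()
  expect_equal(oxygen_uptake_rate(state_vector(), p), 0)
  # (1-Y)/Y = 1 at Y_H = 0.5: OUR equals the growth rate
  p2 <- kinetic_params(Y_H = 0.5, b_H = 1e-9)
  s <- state_vector(S_S = 15, X_H = 1000)
  growth <- process_rates(s, p2, build_petersen(p2, "masm"))[["growth"]]
  expect_equal(oxygen_uptake_rate(s, p2), growth, tolerance = 1e-6)
  # endogenous-only respiration
  s <- state_vector(X_H = 1000)
  expect_equal(oxygen_uptake_rate(s, p), 0.75 * 0.14 * 1000)
  expect_gt(oxygen_uptake_rate(state_vector(S_S = 10, X_H = 10), p), 0)
})
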