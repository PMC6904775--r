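test_that("zero maximal rates freeze the trajectory", {
  net <- toyChain(V = c(0, 0, 0))
  traj <- simulateNetwork(net, times = seq(0, 10, 1))
  for (i in seq_len(nSpecies(net)))
    expect_equal(unname(traj@states[, i]),
                 rep(initialState(net)[[i]], 11), tolerance = 1e-12)
})

test_that("total fluorine is conserved along any trajectory", {
  net <- buildNetwork()
  for (atp in list(atpModel("forced"), atpModel("dynamic"))) {
    traj <- suppressWarnings(
      simulateNetwork(net, times = seq(0, 17, 0.5), atp = atp))
    tf <- traj@observables[, "totalF"]
    expect_lt(max(abs(tf / tf[1] - 1)), 1e-6)
  }
})

test_that("ATP + ADP is conserved in dynamic mode without the sink", {
  net <- buildNetwork()
  traj <- simulateNetwork(net, times = seq(0, 17, 0.5),
                          atp = atpModel("dynamic", kAtp = 0))
  pool <- traj@states[, "ATP"] + traj@states[, "ADP"]
  expect_lt(max(abs(pool / pool[1] - 1)), 1e-6)
})

test_that("the far-sub-saturation limit matches exponential decay", {
  # with Km >> S the irreversible MM step is linear: S(t) = S0 exp(-V t/Km)
  V <- 50; Km <- 1e6; S0 <- 10
  net <- toyIrrPair(V = V, Km = Km, A0 = S0)
  tt <- seq(0, 20, 1)
  traj <- simulateNetwork(net, times = tt)
  expect_equal(unname(traj@states[, "A"]), S0 * exp(-V * tt / Km),
               tolerance = 1e-4)
})

test_that("halving integrator tolerances leaves outputs unchanged to 1e-4", {
  net <- buildNetwork()
  t1 <- suppressWarnings(simulateNetwork(net, times = 0:17,
                                         rtol = 1e-8, atol = 1e-9))
  t2 <- suppressWarnings(simulateNetwork(net, times = 0:17,
                                         rtol = 5e-9, atol = 5e-10))
  rel <- abs(t1@observables - t2@observables) /
    pmax(abs(t2@observables), 1)
  expect_lt(max(rel), 1e-4)
})

test_that("negative excursions stay within integrator-tolerance scale and are never silent", {
  net <- buildNetwork()
  w <- tryCatch({
    simulateNetwork(net, times = 0:17); NULL
  }, warning = function(w) w)
  if (!is.null(w)) {
    expect_match(conditionMessage(w), "clipping")
    m <- regmatches(conditionMessage(w),
                    regexpr("-?[0-9.]+e?-?[0-9]*(?= uM)",
                            conditionMessage(w), perl = TRUE))
    expect_lt(abs(as.numeric(m)), 1e-8 * 1000 * 10)  # 10 x rtol x scale
  }
  succeed()
})

test_that("flux report ranks dominant resultant fluxes with signs", {
  net <- buildNetwork()
  traj <- suppressWarnings(simulateNetwork(net, times = seq(0, 17, 0.5)))
  rep1 <- fluxReport(traj, list(c(1, 4), c(12, 17)), net = net)
  expect_true(all(rep1$rank[rep1$windowStart == 1] ==
                    seq_len(sum(rep1$windowStart == 1))))
  # ranking is by absolute mean flux
  f1 <- rep1$meanFlux[rep1$windowStart == 1]
  expect_true(all(diff(abs(f1)) <= 1e-12))
  # the UDP reductase flux decays toward zero late in the run
  f10 <- traj@fluxes[, "r10"]
  early <- mean(f10[traj@times <= 2])
  late <- mean(f10[traj@times >= 15])
  expect_gt(early, 0)
  expect_lt(abs(late), 0.1 * abs(early))
  expect_error(fluxReport(traj, list(c(3, 3.1))), "fewer than two")
  expect_error(fluxReport(traj, list()), "no windows")
  # all-zero fluxes produce an empty ranking
  frozen <- simulateNetwork(toyChain(V = c(0, 0, 0)), times = 0:5)
  expect_identical(nrow(fluxReport(frozen, list(c(0, 5)))), 0L)
  # a single active reaction is ranked first
  single <- simulateNetwork(toyChain(V = c(4, 0, 0)), times = 0:5)
  expect_identical(fluxReport(single, list(c(0, 5)))$reaction[1], "r1")
})

test_that("steady-state finder honours fixed points and Haldane equilibria", {
  # the all-zero state is a fixed point
  net <- toyRevPair(x0 = c(S = 0, P = 0))
  ss0 <- steadyState(net)
  expect_true(ss0$converged)
  expect_identical(unname(ss0$state), c(0, 0))
  # two-species reversible MM equilibrates at S/P = Vr Kms / (Vf Kmp)
  net <- toyRevPair(Vf = 4, Vr = 2, Kms = 50, Kmp = 20)
  ss <- steadyState(net)
  expect_true(ss$converged)
  expect_equal(ss$state[["S"]] / ss$state[["P"]], 2 * 50 / (4 * 20),
               tolerance = 1e-8)
  # conservation respected by the polish
  expect_equal(sum(ss$state), 100, tolerance = 1e-8)
})

test_that("the depleted-ATP model relaxes to a 5FU/FUDR/ADP steady state", {
  ss <- fullSteadyState()
  expect_true(ss$converged)
  expect_lt(ss$residual, 1e-8)
  expect_true(all(c("5FU", "FUDR", "ADP") %in% ss$nonVanishing))
  # the asymptotic cycle runs through the salvage triangle: reverse flux
  # through the phosphoribosyltransferase, forward through nucleotidase
  # and hydrolase
  expect_lt(ss$fluxes[["r1"]], 0)
  expect_gt(ss$fluxes[["r7"]], 0)
  expect_gt(ss$fluxes[["r9"]], 0)
  expect_equal(ss$fluxes[["r7"]] + 0, ss$fluxes[["r9"]], tolerance = 1e-6)
})
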