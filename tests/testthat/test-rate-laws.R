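test_that("irreversible Michaelis-Menten obeys its defining identities", {
  expect_identical(rateIrrMM(0, V = 12, Km = 7), 0)
  expect_equal(rateIrrMM(7, V = 12, Km = 7), 6)        # half saturation
  # frozen value computed by independent hand evaluation of
  # V*S/(Km+S) at the uridine-hydrolase best-fit parameters
  expect_equal(rateIrrMM(1000, V = 3066.50, Km = 104249), 29.13566875,
               tolerance = 1e-9)
  expect_error(rateIrrMM(-1, V = 1, Km = 1), "non-negative")
  expect_error(rateIrrMM(1, V = 1, Km = 0))
})

test_that("irreversible MM is bounded by V and monotone in S", {
  set.seed(101)
  for (i in 1:200) {
    V <- 10^runif(1, -3, 4); Km <- 10^runif(1, -3, 5)
    S <- sort(10^runif(5, -3, 6))
    v <- vapply(S, rateIrrMM, numeric(1), V = V, Km = Km)
    expect_true(all(v >= 0 & v <= V))
    expect_true(all(diff(v) >= 0))
  }
})

test_that("reversible Michaelis-Menten vanishes exactly on its equilibrium manifold", {
  expect_identical(rateRevMM(0, 0, 1, 1, 1, 1), 0)
  # Haldane balance point: Vf S/Kms = Vr P/Kmp
  p <- c(Vf = 5, Vr = 3, Kms = 70, Kmp = 11)
  P <- 42
  S <- p[["Kms"]] * p[["Vr"]] / p[["Vf"]] * (P / p[["Kmp"]])
  expect_equal(rateRevMM(S, P, p[["Vf"]], p[["Vr"]], p[["Kms"]],
                         p[["Kmp"]]), 0)
  # frozen value from an independent one-line closed-form evaluation at the
  # uracil-phosphoribosyltransferase best-fit parameters
  expect_equal(rateRevMM(100, 10, Vf = 32.25, Vr = 28.2188,
                         Kms = 2572.4, Kmp = 33.443),
               -5.369786729, tolerance = 1e-9)
  expect_error(rateRevMM(-1, 0, 1, 1, 1, 1), "non-negative")
})

test_that("ping-pong rate has the Cleland limits and equilibrium zero", {
  p <- list(Keq = 4.6890, Kia = 2.8129e5, Kiq = 0.89666, Kma = 4.141,
            Kmb = 3.7026e-4, Kmp = 2.18e-3, Kmq = 6.214,
            Vf = 3162.6, Vr = 177.93)
  # thermodynamic equilibrium: A*B = P*Q/Keq
  A <- 3; B <- 5; Q <- 7
  P <- A * B * p$Keq / Q
  expect_equal(do.call(ratePingPong, pingPongArgs(p, A, B, P, Q)), 0)
  # saturation limits
  big <- 1e9 * max(p$Kma, p$Kmb)
  expect_equal(do.call(ratePingPong, pingPongArgs(p, big, big, 0, 0)),
               p$Vf, tolerance = 1e-6)
  expect_equal(do.call(ratePingPong, pingPongArgs(p, 0, 0, 1e12, 1e12)),
               -p$Vr, tolerance = 1e-6)
  # all-zero state is a fixed point, not an error
  expect_identical(do.call(ratePingPong, pingPongArgs(p, 0, 0, 0, 0)), 0)
  # frozen value from an independent evaluation of the adopted closed form
  expect_equal(do.call(ratePingPong, pingPongArgs(p, 1000, 10, 100, 10)),
               1858.031279, tolerance = 1e-8)
  expect_error(do.call(ratePingPong, pingPongArgs(p, -1, 0, 0, 0)),
               "non-negative")
})

test_that("ping-pong rate sign equals the sign of the mass-action displacement", {
  set.seed(202)
  p <- list(Keq = 2.5, Kia = 10, Kiq = 3, Kma = 7, Kmb = 0.4, Kmp = 1.2,
            Kmq = 6, Vf = 50, Vr = 20)
  for (i in 1:1000) {
    s <- 10^runif(4, -2, 3)
    v <- do.call(ratePingPong, pingPongArgs(p, s[1], s[2], s[3], s[4]))
    disp <- s[1] * s[2] - s[3] * s[4] / p$Keq
    expect_identical(sign(v), sign(disp))
  }
})

test_that("all kernels are finite and continuous at the origin", {
  eps <- 1e-12
  expect_lt(abs(rateIrrMM(eps, 5, 3)), 1e-10)
  expect_lt(abs(rateRevMM(eps, eps, 5, 3, 2, 4)), 1e-10)
  p <- list(Keq = 2, Kia = 1, Kiq = 1, Kma = 1, Kmb = 1, Kmp = 1, Kmq = 1,
            Vf = 5, Vr = 5)
  expect_lt(abs(do.call(ratePingPong, pingPongArgs(p, eps, eps, eps, eps))),
            1e-6)
})

test_that("the vectorized network evaluator agrees with the scalar kernels", {
  net <- buildNetwork()
  set.seed(7)
  state <- stats::setNames(10^runif(nSpecies(net), -2, 3), speciesIds(net))
  v <- reactionRates(net, state)
  pars <- reactionParameters(net)
  for (j in seq_len(nReactions(net))) {
    sub <- net@reactions$substrates[[j]]
    prod <- net@reactions$products[[j]]
    p <- pars[[j]]
    expected <- switch(net@reactions$rateLaw[j],
      irr_mm = rateIrrMM(state[[sub[1]]], p[["V"]], p[["Km"]]),
      rev_mm = rateRevMM(state[[sub[1]]], state[[prod[1]]], p[["Vf"]],
                         p[["Vr"]], p[["Kms"]], p[["Kmp"]]),
      ping_pong = ratePingPong(state[[sub[1]]], state[[sub[2]]],
                               state[[prod[1]]], state[[prod[2]]],
                               p[["Keq"]], p[["Kia"]], p[["Kiq"]],
                               p[["Kma"]], p[["Kmb"]], p[["Kmp"]],
                               p[["Kmq"]], p[["Vf"]], p[["Vr"]]))
    expect_equal(unname(v[j]), expected, tolerance = 1e-12)
  }
})
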