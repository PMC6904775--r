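test_that("irreversible MM elasticity has its closed form Km/(Km+S)", {
  net <- toyIrrPair(V = 6, Km = 30)
  for (S in c(5, 30, 200)) {
    st <- c(A = S, B = 10)
    E <- elasticities(net, st)
    expect_equal(E["r1", "A"], 30 / (30 + S), tolerance = 1e-12)
    expect_identical(E["r1", "B"], 0)
  }
  st <- c(A = 30, B = 10)
  expect_equal(elasticities(net, st)["r1", "A"], 0.5)
  # zero concentration yields an undefined (NA) log-derivative, not NaN
  E0 <- elasticities(net, c(A = 10, B = 0))
  expect_true(is.na(E0["r1", "B"]))
  expect_false(any(is.nan(E0)))
})

test_that("analytic elasticities match central finite differences", {
  net <- buildNetwork()
  set.seed(33)
  for (rep in 1:5) {
    st <- stats::setNames(10^runif(16, -1, 3), speciesIds(net))
    E <- elasticities(net, st)
    v0 <- reactionRates(net, st)
    h <- 1e-6
    for (j in sample(22, 6)) {
      for (sp in speciesIds(net)) {
        if (is.na(E[j, sp])) next
        up <- st; up[sp] <- st[sp] * (1 + h)
        dn <- st; dn[sp] <- st[sp] * (1 - h)
        fd <- (reactionRates(net, up)[j] - reactionRates(net, dn)[j]) /
          (2 * h * v0[j])
        expect_equal(unname(E[j, sp]), unname(fd), tolerance = 1e-4)
      }
    }
  }
})

test_that("an unbranched two-step pathway reproduces the textbook control coefficients", {
  net <- toyPathway()
  ss <- steadyState(net)
  expect_true(ss$converged)
  cc <- controlCoefficients(net, ss)
  E <- elasticities(net, ss$state)
  e1 <- E["r1", "S"]; e2 <- E["r2", "S"]
  expect_equal(unname(cc$FCC["r1", ]),
               c(e2 / (e2 - e1), -e1 / (e2 - e1)), tolerance = 1e-8)
  expect_equal(unname(cc$CCC["S", ]),
               c(1 / (e2 - e1), -1 / (e2 - e1)), tolerance = 1e-8)
  expect_equal(sum(cc$FCC["r1", ]), 1, tolerance = 1e-10)
  expect_equal(sum(cc$CCC["S", ]), 0, tolerance = 1e-10)
})

test_that("matrix-method control coefficients agree with steady-state re-solve perturbation", {
  # independent oracle: scale each enzyme's maximal rates by 1 +/- d,
  # re-solve the steady state and take the central log-difference
  net <- toyPathway()
  ss <- steadyState(net)
  cc <- controlCoefficients(net, ss)
  d <- 1e-5
  perturb <- function(k, fac) {
    g <- net@reactions$paramGroup[k]
    n2 <- net
    for (nm in intersect(c("V", "Vf", "Vr"),
                         names(resolveParams(net, g))))
      n2 <- setParameter(n2, g, nm, resolveParams(net, g)[[nm]] * fac)
    steadyState(n2)
  }
  for (k in 1:2) {
    up <- perturb(k, 1 + d); dn <- perturb(k, 1 - d)
    fdJ <- unname(log(up$fluxes[1]) - log(dn$fluxes[1])) / (2 * d)
    fdS <- (log(up$state[["S"]]) - log(dn$state[["S"]])) / (2 * d)
    expect_equal(unname(cc$FCC["r1", k]), fdJ, tolerance = 1e-4)
    expect_equal(unname(cc$CCC["S", k]), fdS, tolerance = 1e-4)
  }
})

test_that("off-steady-state references are accepted with a warning", {
  net <- toyPathway()
  fake <- list(state = initialState(net),
               fluxes = reactionRates(net, initialState(net)),
               converged = FALSE)
  expect_warning(mca(net, fake), "summation theorems")
})

test_that("extreme scan reports degenerate and single-entry matrices correctly", {
  m0 <- matrix(0, 2, 2, dimnames = list(c("r1", "r2"), c("a", "b")))
  res0 <- new("MCAResult", EC = m0, FCC = m0, CCC = m0,
              state = c(a = 1, b = 1), fluxes = c(1, 1),
              atSteadyState = TRUE)
  ex0 <- mcaExtremes(res0)
  expect_identical(nrow(ex0), 0L)
  expect_setequal(attr(ex0, "degenerate"), c("EC", "FCC", "CCC"))

  m1 <- m0; m1["r1", "b"] <- -3.5
  res1 <- new("MCAResult", EC = m1, FCC = m0, CCC = m0,
              state = c(a = 1, b = 1), fluxes = c(1, 1),
              atSteadyState = TRUE)
  ex1 <- mcaExtremes(res1)
  expect_identical(nrow(ex1), 1L)
  expect_identical(ex1$cause, "b")
  expect_identical(ex1$effect, "r1")
  expect_identical(ex1$value, -3.5)
})

test_that("full-model extremes mirror the published table layout", {
  ss <- fullSteadyState()
  res <- mca(buildNetwork(), ss)
  ex <- mcaExtremes(res)
  expect_setequal(unique(ex$coefficient), c("EC", "FCC", "CCC"))
  expect_true(all(c("Max. neg.", "Max. pos.") %in% ex$extreme))
  # the asymptotic cycle is unbranched, so FCC extremes cannot exceed 1
  fvals <- ex$value[ex$coefficient == "FCC"]
  expect_true(all(abs(fvals) <= 1 + 1e-6))
})
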