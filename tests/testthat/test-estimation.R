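test_that("weighted least-squares objective is zero at the generating truth and linear in weights", {
  net <- toyChain()
  tc <- generateTimeCourse(net, times = seq(1, 10, 1), noiseSd = 0)
  expect_lt(wlsObjective(net, tc$observed), 1e-12)
  noisy <- generateTimeCourse(net, times = seq(1, 10, 1), noiseSd = 0.1,
                              seed = 3)$observed
  w <- stats::setNames(rep(1, 5), c("A", "B", "C", "D", "totalF"))
  o1 <- wlsObjective(net, noisy, weights = w)
  o2 <- wlsObjective(net, noisy, weights = 2 * w)
  expect_gt(o1, 0)
  expect_equal(o2, 2 * o1, tolerance = 1e-12)
  expect_error(wlsObjective(net, noisy, weights = -w), "positive")
  expect_error(wlsObjective(net, data.frame(time = 1:3, bogus = 1:3)),
               "no known observable")
})

test_that("a dense grid scan locates the objective minimum at the generating value", {
  net <- toyIrrPair(V = 6, Km = 30)
  tc <- generateTimeCourse(net, times = seq(1, 10, 1), noiseSd = 0)
  grid <- seq(log10(2), log10(18), length.out = 61)
  obj <- vapply(grid, function(lv)
    wlsObjective(setParameter(net, "t1", "V", 10^lv), tc$observed),
    numeric(1))
  expect_equal(10^grid[which.min(obj)], 6, tolerance = 0.05)
})

test_that("Hooke-Jeeves solves convex problems and flags active bounds", {
  r <- hookeJeeves(function(x) sum((x - c(1, -2))^2), c(5, 5),
                   tol = 1e-8, itLim = 300)
  expect_equal(r$par, c(1, -2), tolerance = 1e-6)
  expect_true(r$converged)
  # bound-constrained optimum lands on the bound and is flagged
  rb <- hookeJeeves(function(x) (x - 3)^2, x0 = 1, lower = 0, upper = 2,
                    tol = 1e-8, itLim = 300)
  expect_equal(rb$par, 2, tolerance = 1e-7)
  expect_true(rb$boundsActive)
  expect_error(hookeJeeves(function(x) NaN, 0), "not finite")
})

test_that("Hooke-Jeeves beats a 200 x 200 grid refinement on the Rosenbrock valley", {
  rb <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  g <- seq(-2, 2, length.out = 200)
  gridMin <- min(outer(g, g, Vectorize(function(a, b) rb(c(a, b)))))
  x <- c(-1.2, 1); f <- rb(x)
  # consecutive restarts, as in the staged estimation protocol
  for (s in 1:60) {
    r <- hookeJeeves(rb, x, lower = -2, upper = 2, rho = 0.2,
                     tol = 1e-7, itLim = 50)
    if (f - r$value < 1e-10) break
    x <- r$par; f <- r$value
  }
  expect_lte(f, gridMin)
})

test_that("Hooke-Jeeves matches exhaustive grid search within two grid cells", {
  f2 <- function(x) (x[1] - 0.73)^2 + 2 * (x[2] + 0.41)^2 +
    0.3 * sin(3 * x[1]) * sin(3 * x[2])
  lo <- c(-2, -2); hi <- c(2, 2)
  g <- seq(lo[1], hi[1], length.out = 101)
  cell <- diff(g)[1]
  vals <- outer(g, g, Vectorize(function(a, b) f2(c(a, b))))
  best <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  gridPar <- c(g[best[1]], g[best[2]])
  x <- c(0, 0); fv <- f2(x)
  for (s in 1:30) {
    r <- hookeJeeves(f2, x, lo, hi, tol = 1e-7, itLim = 50)
    if (fv - r$value < 1e-12) break
    x <- r$par; fv <- r$value
  }
  expect_lt(max(abs(x - gridPar)), 2 * cell)
})

test_that("multi-start fit recovers a 2-parameter model from noiseless data within 1%", {
  net <- toyIrrPair(V = 6, Km = 30)
  tc <- generateTimeCourse(net, times = seq(1, 10, 1), noiseSd = 0)
  fit <- multistartFit(net, tc$observed, free = c("t1.V", "t1.Km"),
                       nAttempts = 5, seed = 11)
  expect_lt(max(abs(fit@par$bfv / c(6, 30) - 1)), 0.01)
  expect_true(all(is.finite(fit@par$devStds)))
  expect_true(all(fit@par$stds >= 0))
  # the retained set holds the most accurate attempts
  att <- fit@attempts
  expect_lte(max(att$objective[att$retained]),
             min(att$objective[!att$retained], Inf))
  # objective never rises within an attempt
  expect_true(all(att$objective <= att$startObjective + 1e-12))
})

test_that("multi-start fitting is bit-reproducible from its seed", {
  net <- toyIrrPair()
  tc <- generateTimeCourse(net, times = seq(1, 8, 1), noiseSd = 0.05,
                           seed = 9)
  f1 <- multistartFit(net, tc$observed, free = c("t1.V", "t1.Km"),
                      nAttempts = 5, seed = 4)
  f2 <- multistartFit(net, tc$observed, free = c("t1.V", "t1.Km"),
                      nAttempts = 5, seed = 4)
  expect_identical(f1@par, f2@par)
  expect_identical(f1@attempts, f2@attempts)
})

test_that("identical attempts give zero spread and devStds 0 by convention", {
  net <- toyIrrPair()
  tc <- generateTimeCourse(net, times = seq(1, 8, 1), noiseSd = 0)
  # zero-width bounds force every attempt through the same deterministic path
  fit <- multistartFit(net, tc$observed, free = c("t1.V", "t1.Km"),
                       nAttempts = 5, seed = 2, decades = 0)
  expect_identical(fit@par$stds, c(0, 0))
  expect_identical(fit@par$devStds, c(0, 0))
})

test_that("guard rails reject unusable protocols and starts", {
  net <- toyIrrPair()
  tc <- generateTimeCourse(net, times = 1:5, noiseSd = 0)
  expect_error(multistartFit(net, tc$observed, free = c("t1.V", "t1.Km"),
                             nAttempts = 2), "at least")
  expect_error(fitProtocol(rho = 1.2))
  expect_error(fitProtocol(tol = 0))
})
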