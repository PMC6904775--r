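# Small networks built with the package's own constructor, used across the
# suite. All are fluorine-free toys except where noted; observables map each
# species to itself plus a conserved total.

toyIrrPair <- function(V = 6, Km = 30, A0 = 300) {
  sp <- data.frame(id = c("A", "B"), initial = c(A0, 0),
                   fluorinated = TRUE, boundary = FALSE)
  rx <- data.frame(index = 1L, ec = "toy.irr", name = "step",
                   rateLaw = "irr_mm", paramGroup = "t1",
                   hypothetical = FALSE)
  rx$substrates <- list("A"); rx$products <- list("B")
  reactionNetwork(sp, rx, list(t1 = c(V = V, Km = Km)),
                  observables = list(A = "A", B = "B",
                                     totalF = c("A", "B")))
}

toyRevPair <- function(Vf = 4, Vr = 2, Kms = 50, Kmp = 20,
                       x0 = c(S = 90, P = 10)) {
  sp <- data.frame(id = names(x0), initial = unname(x0),
                   fluorinated = TRUE, boundary = FALSE)
  rx <- data.frame(index = 1L, ec = "toy.rev", name = "rev",
                   rateLaw = "rev_mm", paramGroup = "g",
                   hypothetical = FALSE)
  rx$substrates <- list("S"); rx$products <- list("P")
  reactionNetwork(sp, rx,
                  list(g = c(Vf = Vf, Vr = Vr, Kms = Kms, Kmp = Kmp)),
                  observables = list(S = "S", P = "P",
                                     totalF = c("S", "P")))
}

toyChain <- function(V = c(8, 5, 3), Km = c(40, 60, 25),
                     x0 = c(A = 300, B = 10, C = 5, D = 0)) {
  sp <- data.frame(id = names(x0), initial = unname(x0),
                   fluorinated = TRUE, boundary = FALSE)
  rx <- data.frame(index = 1:3, ec = paste0("toy.", 1:3),
                   name = paste0("step", 1:3), rateLaw = "irr_mm",
                   paramGroup = paste0("t", 1:3), hypothetical = FALSE)
  rx$substrates <- list("A", "B", "C")
  rx$products <- list("B", "C", "D")
  pg <- list(t1 = c(V = V[1], Km = Km[1]), t2 = c(V = V[2], Km = Km[2]),
             t3 = c(V = V[3], Km = Km[3]))
  reactionNetwork(sp, rx, pg,
                  observables = list(A = "A", B = "B", C = "C", D = "D",
                                     totalF = names(x0)))
}

# unbranched 2-step pathway between fixed boundary pools; its flux control
# coefficients have the textbook closed form from the elasticities at S
toyPathway <- function() {
  sp <- data.frame(id = c("X0", "S", "X1"), initial = c(100, 20, 0),
                   fluorinated = FALSE, boundary = c(TRUE, FALSE, TRUE))
  rx <- data.frame(index = 1:2, ec = c("e1", "e2"), name = c("e1", "e2"),
                   rateLaw = c("rev_mm", "irr_mm"),
                   paramGroup = c("a", "b"), hypothetical = FALSE)
  rx$substrates <- list("X0", "S"); rx$products <- list("S", "X1")
  reactionNetwork(sp, rx,
                  list(a = c(Vf = 10, Vr = 3, Kms = 40, Kmp = 30),
                       b = c(V = 6, Km = 25)),
                  observables = list())
}

# memoized full-model steady state: several tests share it and it is the
# expensive reference computation
fullSteadyState <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(steadyState(buildNetwork()))
    cache
  }
})

pingPongArgs <- function(p, A, B, P, Q)
  c(list(A = A, B = B, P = P, Q = Q), as.list(p))
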