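test_that("model construction validates shapes, labels and stochasticity", {
    m <- twoStateModel()
    expect_s4_class(m, "GenerativeModel")
    expect_identical(states(m), c("s1", "s2"))
    expect_identical(actions(m), "advance")

    # non-stochastic columns are rejected, not renormalised
    expect_error(generativeModel(c("a", "b"), c("x", "y"),
                                 A = matrix(c(0.9, 0.2, 0.2, 0.8), 2),
                                 B = diag(2), D = c(1, 0)),
                 "non-stochastic")
    expect_error(generativeModel(c("a", "a"), c("x", "y"), diag(2),
                                 diag(2), c(1, 0)), "unique")
    expect_error(generativeModel(c("a", "b"), c("x", "y"), diag(2),
                                 diag(2), c(0.7, 0.2)), "sum to 1")
    # a tiny deviation within tolerance is accepted
    expect_s4_class(generativeModel(c("a", "b"), c("x", "y"), diag(2),
                                    diag(2), c(1 - 1e-12, 1e-12)),
                    "GenerativeModel")
})

test_that("joint probability multiplies D, A and B factors", {
    fg <- configModel(loadBundled("foraging_grid"))
    expect_identical(
        jointProbability(fg, c("up-left", "up-right"), c("blue", "yellow")),
        1)
    expect_identical(
        jointProbability(fg, c("up-left", "up-right"), c("yellow", "yellow")),
        0)
    expect_equal(jointProbability(twoStateModel(), "s1", "o1"), 0.45,
                 tolerance = 1e-12)
    expect_error(jointProbability(fg, "nowhere", "blue"), "unknown state")
    expect_error(jointProbability(fg, c("up-left", "up-right"), "blue"),
                 "equal length")
})

test_that("joint probability sums to one over all sequence pairs", {
    m <- twoStateModel()
    T <- 3L
    combos <- expand.grid(rep(list(states(m)), T), stringsAsFactors = FALSE)
    obsCombos <- expand.grid(rep(list(observations(m)), T),
                             stringsAsFactors = FALSE)
    total <- 0
    for (i in seq_len(nrow(combos)))
        for (j in seq_len(nrow(obsCombos)))
            total <- total + jointProbability(
                m, as.character(combos[i, ]), as.character(obsCombos[j, ]))
    expect_equal(total, 1, tolerance = 1e-9)
})

test_that("forward filtering matches Bayes on closed-form cases", {
    # uninformative likelihood: posterior equals the prior predictive
    flat <- generativeModel(c("a", "b"), c("x", "y"),
                            A = matrix(0.5, 2, 2),
                            B = matrix(c(0.3, 0.7, 0.6, 0.4), 2),
                            D = c(0.2, 0.8))
    post <- forwardFilter(flat, c("x", "y", "x"))
    expect_equal(unname(beliefProbs(post[[1]])), c(0.2, 0.8),
                 tolerance = 1e-12)
    expect_equal(unname(beliefProbs(post[[2]])),
                 as.numeric(matrix(c(0.3, 0.7, 0.6, 0.4), 2) %*% c(0.2, 0.8)),
                 tolerance = 1e-12)

    fg <- configModel(loadBundled("foraging_grid"))
    b1 <- beliefProbs(forwardFilter(fg, "blue")[[1]])
    expect_equal(unname(b1), c(1, 0, 0, 0))

    b <- beliefProbs(forwardFilter(twoStateModel(), "o1")[[1]])
    expect_equal(unname(b), c(0.45, 0.1) / 0.55, tolerance = 1e-12)
})

test_that("zero-likelihood evidence raises an explicit error", {
    fg <- configModel(loadBundled("foraging_grid"))
    # blue then red is impossible under the deterministic reading cycle
    expect_error(forwardFilter(fg, c("blue", "red")), "degenerate evidence")
    expect_error(forwardFilter(fg, character(0)), "non-empty")
})

test_that("filtering agrees with brute-force enumeration on random models", {
    set.seed(42)
    worst <- 0
    for (i in 1:25) {
        nS <- sample(2:4, 1)
        nO <- sample(2:4, 1)
        T <- sample(1:5, 1)
        m <- randomModel(nS, nO)
        obs <- sample(observations(m), T, replace = TRUE)
        got <- t(vapply(forwardFilter(m, obs), beliefProbs, numeric(nS)))
        want <- oracleFilterPosteriors(likelihood(m), transitions(m, 1L),
                                       initialDist(m),
                                       match(obs, observations(m)))
        worst <- max(worst, max(abs(got - want)))
    }
    expect_lt(worst, 1e-10)
})

test_that("state forecasting iterates the transition slice", {
    fg <- configModel(loadBundled("foraging_grid"))
    b <- beliefState(c(1, 0, 0, 0), time = 1L, states = states(fg))
    f <- predictStates(fg, b, horizon = 1)
    expect_equal(unname(beliefProbs(f[[1]])), c(0, 1, 0, 0))
    # a full lap of the 2x2 grid returns to the start
    f4 <- predictStates(fg, b, horizon = 4)
    expect_equal(beliefProbs(f4[[4]]), beliefProbs(b))
    expect_equal(beliefTime(f4[[4]]), 5L)

    ident <- twoStateModel()  # identity B
    b2 <- beliefState(c(0.3, 0.7), states = states(ident))
    expect_equal(beliefProbs(predictStates(ident, b2, 7)[[7]]),
                 beliefProbs(b2))

    mix <- generativeModel(c("a", "b"), c("x", "y"), diag(2),
                           B = matrix(0.5, 2, 2), D = c(1, 0))
    expect_equal(unname(beliefProbs(
        predictStates(mix, beliefState(c(1, 0), states = c("a", "b")),
                      1)[[1]])), c(0.5, 0.5))
})

test_that("observation prediction marginalises the likelihood", {
    fg <- configModel(loadBundled("foraging_grid"))
    b <- beliefState(c(0, 1, 0, 0), states = states(fg))
    expect_equal(unname(predictObservations(fg, b)), c(0, 1, 0, 0))

    # deterministic square A maps a uniform belief to a uniform predictive
    b4 <- beliefState(rep(0.25, 4), states = states(fg))
    expect_equal(unname(predictObservations(fg, b4)), rep(0.25, 4))

    m <- twoStateModel()
    b2 <- beliefState(c(9, 2) / 11, states = states(m))
    expect_equal(unname(predictObservations(m, b2)),
                 c(8.5, 2.5) / 11, tolerance = 1e-12)
})

test_that("trajectory simulation is seeded, pure and law-abiding", {
    fg <- configProcess(loadBundled("foraging_grid"))
    t1 <- simulateTrajectory(fg, 2, seed = 7)
    expect_identical(t1$state, c("up-left", "up-right"))
    expect_identical(t1$observation, c("blue", "yellow"))

    # identical seed, identical output; different seed may differ
    proc <- asGenerativeProcess(randomModel(3, 3))
    expect_identical(simulateTrajectory(proc, 50, seed = 11),
                     simulateTrajectory(proc, 50, seed = 11))

    # the caller's RNG stream is not consumed
    set.seed(99)
    before <- runif(1)
    set.seed(99)
    invisible(simulateTrajectory(proc, 20, seed = 3))
    expect_identical(runif(1), before)

    # long-run transition frequencies match the generating B
    B <- matrix(c(0.7, 0.3, 0.4, 0.6), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    p2 <- generativeProcess(c("a", "b"), c("x", "y"),
                            A = diag(2), B = B, D = c(0.5, 0.5))
    traj <- simulateTrajectory(p2, 10000, seed = 123)
    emp <- table(traj$state[-1], traj$state[-nrow(traj)])
    emp <- sweep(emp, 2, colSums(emp), "/")
    expect_lt(max(colSums(abs(emp - B))), 0.05)
})
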