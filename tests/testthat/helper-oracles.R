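# Independent oracles and random-instance generators used across the suite.
# The oracles work straight from the raw matrices by exhaustive enumeration,
# so they share no code path with the package's recursions.

# Filtering posterior Q(s_t | o_{1:t}) by brute-force summation over all
# state sequences of length t. A: |O| x |S|; B: |S| x |S|; oi: observation
# indices. Returns a T x |S| matrix of posteriors.
oracleFilterPosteriors <- function(A, B, D, oi) {
    S <- length(D)
    T <- length(oi)
    out <- matrix(NA_real_, T, S)
    for (t in seq_len(T)) {
        seqs <- as.matrix(expand.grid(rep(list(seq_len(S)), t)))
        post <- numeric(S)
        for (r in seq_len(nrow(seqs))) {
            ss <- seqs[r, ]
            p <- D[ss[1L]] * A[oi[1L], ss[1L]]
            if (t >= 2L)
                for (k in 2:t)
                    p <- p * B[ss[k], ss[k - 1L]] * A[oi[k], ss[k]]
            post[ss[t]] <- post[ss[t]] + p
        }
        out[t, ] <- post / sum(post)
    }
    out
}

# Mutual information between state and observation for joint
# p(s, o) = q[s] * A[o, s], via the entropy identity I = H(S) + H(O) - H(S,O).
oracleMutualInformation <- function(A, q) {
    joint <- sweep(A, 2L, q, "*")   # |O| x |S|
    ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    ent(colSums(joint)) + ent(rowSums(joint)) - ent(as.numeric(joint))
}

# Random column-stochastic matrix with strictly positive entries.
randomStochasticMatrix <- function(nrow, ncol) {
    M <- matrix(stats::rgamma(nrow * ncol, shape = 1) + 1e-6, nrow, ncol)
    sweep(M, 2L, colSums(M), "/")
}

# Random small model with strictly positive parameters (so every observation
# sequence has positive likelihood).
randomModel <- function(nStates, nObs) {
    generativeModel(
        states = paste0("s", seq_len(nStates)),
        observations = paste0("o", seq_len(nObs)),
        A = randomStochasticMatrix(nObs, nStates),
        B = randomStochasticMatrix(nStates, nStates),
        D = as.numeric(randomStochasticMatrix(nStates, 1L)),
        name = "random")
}

# A non-degenerate knapping-tool generative process: shapes afford their
# characteristic function most of the time, shapes both persist and progress,
# and all three shapes are reachable from a uniform start.
mixedKnappingProcess <- function() {
    shapes <- c("rounded", "squared", "sharp")
    fns <- c("crushing", "cracking", "cutting")
    A <- matrix(c(0.70, 0.20, 0.10,
                  0.15, 0.70, 0.15,
                  0.10, 0.20, 0.70), 3, 3,
                dimnames = list(fns, shapes))
    B <- matrix(c(0.60, 0.30, 0.10,
                  0.10, 0.60, 0.30,
                  0.10, 0.10, 0.80), 3, 3,
                dimnames = list(shapes, shapes))
    generativeProcess(shapes, fns, A, B, D = rep(1 / 3, 3),
                      name = "knapping_mixed")
}

# Two-state fixture used in several closed-form checks: flat prior, columns
# [0.9, 0.1] and [0.2, 0.8].
twoStateModel <- function() {
    generativeModel(c("s1", "s2"), c("o1", "o2"),
                    A = matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2),
                    B = diag(2), D = c(0.5, 0.5), name = "two-state")
}
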