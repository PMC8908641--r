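randomCovInstance <- function(seed, C = 60L, G = 3L, n = 2L) {
    set.seed(seed)
    mu <- lapply(seq_len(G), function(g) rnorm(n, sd = 3))
    truth <- sample.int(G, C, replace = TRUE)
    x <- t(vapply(truth, function(g) mu[[g]] + rnorm(n, sd = 0.5),
        numeric(n)))
    p <- matrix(rgamma(C * G, 1), C, G)
    p <- p / rowSums(p)
    list(x = x, p = p, truth = truth, mu = mu)
}

test_that("objective: zero KL at the fixed point and closed forms", {
    inst <- randomCovInstance(1)
    m <- covMStep(inst$p, inst$x, inst$p, W = 0.5)
    # pi == pSvm: the regularization term contributes exactly zero
    llOnly <- coverageObjective(inst$x, inst$p, inst$p, m$mu, m$Sigma,
        W = 0.5)
    expect_equal(llOnly,
        coverageObjective(inst$x, inst$p, inst$p, m$mu, m$Sigma, W = 99))
    # KL((1,0) || (0.5,0.5)) = ln 2
    x1 <- matrix(0, 1, 1)
    mu1 <- list(0, 0)
    S1 <- list(matrix(1), matrix(1))
    p1 <- matrix(c(1, 0), 1)
    piU <- matrix(0.5, 1, 2)
    expect_equal(
        coverageObjective(x1, p1, piU, mu1, S1, W = 0) -
            coverageObjective(x1, p1, piU, mu1, S1, W = 1),
        log(2))
    # G = 1 reduces to the plain Gaussian log-likelihood
    xg <- matrix(rnorm(10), 10, 1)
    obj1 <- coverageObjective(xg, matrix(1, 10, 1), matrix(1, 10, 1),
        list(0.2), list(matrix(0.8)), W = 1)
    expect_equal(obj1, sum(dnorm(xg, 0.2, sqrt(0.8), log = TRUE)))
})

test_that("E-step matches the naive Gaussian-ratio oracle", {
    inst <- randomCovInstance(2, C = 2L, G = 2L)
    m <- covMStep(inst$p, inst$x, inst$p, W = 0.5)
    pi <- m$pi
    r <- covEStep(inst$x, pi, m$mu, m$Sigma)
    expect_equal(r, oracleCovEStep(inst$x, pi, m$mu, m$Sigma),
        tolerance = 1e-9)
    # identical components with uniform priors: r = 1/G
    same <- covEStep(inst$x, matrix(0.5, 2, 2), list(c(0, 0), c(0, 0)),
        list(diag(2), diag(2)))
    expect_equal(same, matrix(0.5, 2, 2))
    # a zero prior annihilates the component regardless of density
    pin <- matrix(c(1, 1, 0, 0), 2, 2)
    r0 <- covEStep(inst$x, pin, m$mu, m$Sigma)
    expect_equal(r0, matrix(c(1, 1, 0, 0), 2, 2))
})

test_that("M-step matches the naive transcription and the blend rule", {
    inst <- randomCovInstance(3, C = 3L, G = 2L)
    set.seed(33)
    r <- matrix(rgamma(6, 1), 3, 2)
    r <- r / rowSums(r)
    got <- covMStep(r, inst$x, inst$p[, 1:2] / rowSums(inst$p[, 1:2]),
        W = 0.5, ridge = 0)
    want <- oracleCovMStep(r, inst$x,
        inst$p[, 1:2] / rowSums(inst$p[, 1:2]), W = 0.5)
    expect_equal(got$pi, want$pi, tolerance = 1e-9)
    expect_equal(got$mu, want$mu, tolerance = 1e-9)
    expect_equal(got$Sigma, want$Sigma, tolerance = 1e-9)
    # r = pSvm is a fixed point of the prior blend for any W
    for (W in c(0.1, 1, 7))
        expect_equal(covMStep(r, inst$x, r, W)$pi, r, tolerance = 1e-12)
    # hand case: r = (1,0), p = (0,1), W = 1 -> pi = (0.5, 0.5)
    h <- covMStep(matrix(c(1, 0), 1, 2), matrix(0, 1, 2),
        matrix(c(0, 1), 1, 2), W = 1)
    expect_equal(unname(h$pi), matrix(0.5, 1, 2), tolerance = 1e-12)
    # pi rows sum to one exactly (algebraic identity of the blend)
    expect_equal(rowSums(got$pi), rep(1, 3), tolerance = 1e-12)
})

test_that("the default regularization weight is one over the sample count", {
    inst <- randomCovInstance(4, n = 2L)
    fit <- runCoverageGmm(inst$x, inst$p)
    expect_equal(formals(runCoverageGmm)$W, quote(1 / ncol(x)))
    expect_equal(eval(formals(runCoverageGmm)$W,
        list(x = inst$x)), 0.5)
    expect_true(length(fit$objective) >= 2)
})

test_that("the objective is non-decreasing over EM on random instances", {
    for (s in 1:20) {
        inst <- randomCovInstance(100 + s)
        fit <- runCoverageGmm(inst$x, inst$p, W = 0.5, maxIter = 50L)
        expect_true(all(diff(fit$objective) >= -1e-8),
            info = paste("seed", s))
    }
})

test_that("a dominant prior forces the prior's assignment", {
    inst <- randomCovInstance(5)
    oneHot <- matrix(0, 60, 3)
    oneHot[cbind(1:60, inst$truth)] <- 1
    fit <- runCoverageGmm(inst$x, oneHot, W = 1e6, maxIter = 50L)
    expect_equal(fit$assignment, inst$truth)
})

test_that("a single component absorbs everything with the weighted mean", {
    x <- matrix(rnorm(20), 10, 2)
    fit <- runCoverageGmm(x, matrix(1, 10, 1))
    expect_equal(fit$assignment, rep(1L, 10))
    expect_equal(fit$mu[[1]], colMeans(x), tolerance = 1e-9)
})

test_that("well-separated components with informative priors are recovered", {
    set.seed(77)
    C <- 200L
    truth <- sample.int(2L, C, replace = TRUE)
    mu <- list(c(1, 1), c(3, 3))
    x <- t(vapply(truth, function(g) mu[[g]] + rnorm(2, sd = 0.2),
        numeric(2)))
    p <- matrix(0.2, C, 2)
    p[cbind(1:C, truth)] <- 0.8
    fit <- runCoverageGmm(x, p, W = 0.5)
    expect_equal(fit$assignment, truth)
})
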