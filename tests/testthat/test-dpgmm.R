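test_that("M-step matches the naive transcription of the updates", {
    rs <- randomDpgmmState(C = 3L, d = 2L, G = 3L, seed = 11)
    got <- mStepDpgmm(rs$state, rs$x, rs$w)
    want <- oracleMStepDpgmm(rs$state, rs$x, rs$w)
    expect_equal(unname(got$gamma), want$gamma, tolerance = 1e-9)
    expect_equal(unname(got$kappa), want$kappa, tolerance = 1e-9)
    expect_equal(unname(got$v), want$v, tolerance = 1e-9)
    expect_equal(unname(got$mu), want$mu, tolerance = 1e-9)
    expect_equal(unname(got$Psi), want$Psi, tolerance = 1e-9)
})

test_that("E-step matches the naive transcription of the updates", {
    rs <- randomDpgmmState(C = 2L, d = 2L, G = 2L, seed = 7)
    st <- mStepDpgmm(rs$state, rs$x, rs$w)
    got <- eStepDpgmm(st, rs$x)
    expect_equal(unname(got$r), oracleEStepDpgmm(st, rs$x),
        tolerance = 1e-9)
    expect_equal(rowSums(got$r), rep(1, 2), tolerance = 1e-12)
})

test_that("single-component M-step collapses the stick parameters", {
    rs <- randomDpgmmState(C = 4L, d = 2L, G = 1L, seed = 2)
    rs$state$r <- matrix(1, 4, 1)
    st <- mStepDpgmm(rs$state, rs$x, rs$w)
    expect_equal(st$gamma[1, 1], 1 + sum(rs$w))
    expect_equal(st$gamma[1, 2], 1)  # alpha, no later components
})

test_that("zero-responsibility components fall back to the priors", {
    rs <- randomDpgmmState(C = 4L, d = 2L, G = 3L, seed = 5)
    rs$state$r[, 2] <- 0
    rs$state$r <- rs$state$r / rowSums(rs$state$r)
    st <- mStepDpgmm(rs$state, rs$x, rs$w)
    expect_equal(st$gamma[2, 1], 1)
    expect_equal(st$kappa[2], 1e-4)
    expect_equal(st$v[2], 2)
    expect_equal(st$Psi[, , 2], rs$state$Psi0)
})

test_that("identical components split responsibility by stick prior only", {
    rs <- randomDpgmmState(C = 5L, d = 2L, G = 2L, seed = 9)
    st <- mStepDpgmm(rs$state, rs$x, rs$w)
    st$gamma[2, ] <- st$gamma[1, ]
    st$kappa[2] <- st$kappa[1]
    st$v[2] <- st$v[1]
    st$mu[2, ] <- st$mu[1, ]
    st$Psi[, , 2] <- st$Psi[, , 1]
    r <- eStepDpgmm(st, rs$x)$r
    # data terms cancel: the odds reduce to the expected stick factor
    # exp(E log beta_1) / exp(E log beta_2 + E log(1 - beta_1))
    g1 <- st$gamma[1, 1]
    g2 <- st$gamma[1, 2]
    expect_equal(unname(r[, 1] / r[, 2]),
        rep(exp(digamma(g1 + g2) - digamma(g2)), 5), tolerance = 1e-9)
    # G = 1 normalizes to all ones
    rs1 <- randomDpgmmState(C = 3L, d = 2L, G = 1L, seed = 4)
    st1 <- mStepDpgmm(rs1$state, rs1$x, rs1$w)
    expect_equal(unname(eStepDpgmm(st1, rs1$x)$r), matrix(1, 3, 1))
})

test_that("dissolution removes small components and renormalizes rows", {
    rs <- randomDpgmmState(C = 3L, d = 2L, G = 3L, seed = 1)
    st <- mStepDpgmm(rs$state, rs$x, rs$w)
    st$r <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.8, 0.1), c(0.2, 0.1, 0.7))
    lengths <- c(2e6, 1e6, 4e5)  # comp 3's only contig is 0.4 Mb
    out <- dissolveSmallComponents(st, lengths, 5e5)
    expect_equal(out$G, 2L)
    expect_equal(unname(out$r[1, ]), c(0.625, 0.375))
    expect_equal(rowSums(out$r), rep(1, 3), tolerance = 1e-12)
    # nothing under threshold: identity
    expect_identical(dissolveSmallComponents(st, c(2e6, 1e6, 6e5), 5e5),
        st)
    # all under threshold: the largest survives
    expect_warning(
        keepOne <- dissolveSmallComponents(st, c(3e5, 2e5, 1e5), 5e5),
        "largest")
    expect_equal(keepOne$G, 1L)
})

test_that("the first layer recovers two well-separated groups", {
    skip_if_not_installed("mclust")
    aris <- vapply(1:10, function(s) {
        set.seed(1000 + s)
        C <- 120L
        truth <- rep(1:2, each = C / 2)
        x <- matrix(rnorm(C * 2, sd = 1), C, 2)
        x[truth == 2, ] <- x[truth == 2, ] + 10
        # each group totals ~0.72 Mb, so any split piece of a group falls
        # under the 0.5 Mb dissolution threshold and gets pruned
        lens <- rep(1.2e4, C)
        fit <- runFirstLayer(x, rep(1, C), lens, GInit = 6L, seed = s)
        mclust::adjustedRandIndex(fit$assignment, truth)
    }, numeric(1))
    expect_true(all(aris >= 0.99))
})

test_that("responsibility rows stay normalized and contigs conserved", {
    rs <- randomDpgmmState(C = 40L, d = 3L, G = 5L, seed = 77)
    fit <- runFirstLayer(rs$x, rs$w, runif(40, 1e5, 1e6), GInit = 5L,
        seed = 3)
    expect_equal(rowSums(fit$state$r), rep(1, 40), tolerance = 1e-9)
    members <- sort(unlist(lapply(fit$clusters, `[[`, "members")))
    expect_identical(members, 1:40)
})

test_that("clusters exceeding the profile-distance cutoff are abnormal", {
    set.seed(12)
    C <- 30L
    x <- matrix(rnorm(C * 2), C, 2)
    prof <- matrix(0.1, C, 4)
    prof[1:15, 1] <- prof[1:15, 1] + 0.1  # two composition blobs 0.1 apart
    fit <- runFirstLayer(x, rep(1, C), rep(1e6, C), GInit = 1L,
        kmerProfiles = prof, maxDistance = 0.04, seed = 1)
    expect_true(any(vapply(fit$clusters, `[[`, logical(1), "abnormal")))
    fit2 <- runFirstLayer(x, rep(1, C), rep(1e6, C), GInit = 1L,
        kmerProfiles = matrix(0.1, C, 4), maxDistance = 0.04, seed = 1)
    expect_false(any(vapply(fit2$clusters, `[[`, logical(1), "abnormal")))
})
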