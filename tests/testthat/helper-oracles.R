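# Independent, naively-looped transcriptions of the model updates, used as
# oracles against the vectorized implementations.

oracleMStepDpgmm <- function(state, x, w) {
    G <- state$G
    C <- nrow(x)
    d <- ncol(x)
    r <- state$r
    out <- list(gamma = matrix(0, G, 2), kappa = numeric(G),
        v = numeric(G), mu = matrix(0, G, d),
        Psi = array(0, c(d, d, G)))
    for (g in seq_len(G)) {
        N <- 0
        for (cc in seq_len(C)) N <- N + w[cc] * r[cc, g]
        out$gamma[g, 1] <- 1 + N
        tailSum <- 0
        if (g < G)
            for (cc in seq_len(C))
                for (gp in (g + 1):G)
                    tailSum <- tailSum + w[cc] * r[cc, gp]
        out$gamma[g, 2] <- state$alpha + tailSum
        out$kappa[g] <- state$kappa0 + N
        acc <- state$kappa0 * state$mu0
        for (cc in seq_len(C)) acc <- acc + w[cc] * r[cc, g] * x[cc, ]
        out$mu[g, ] <- acc / out$kappa[g]
        xbar <- rep(0, d)
        for (cc in seq_len(C)) xbar <- xbar + w[cc] * r[cc, g] * x[cc, ]
        xbar <- xbar / N
        P <- state$Psi0
        for (cc in seq_len(C)) {
            dev <- x[cc, ] - xbar
            P <- P + w[cc] * r[cc, g] * (dev %o% dev)
        }
        devb <- xbar - state$mu0
        P <- P + (state$kappa0 * N / out$kappa[g]) * (devb %o% devb)
        out$Psi[, , g] <- P
        out$v[g] <- state$v0 + N
    }
    out
}

oracleEStepDpgmm <- function(state, x) {
    G <- state$G
    C <- nrow(x)
    d <- ncol(x)
    r <- matrix(0, C, G)
    for (cc in seq_len(C)) {
        logu <- numeric(G)
        for (g in seq_len(G)) {
            g1 <- state$gamma[g, 1]
            g2 <- state$gamma[g, 2]
            term <- digamma(g1) - digamma(g1 + g2)
            if (g > 1)
                for (gp in seq_len(g - 1))
                    term <- term + digamma(state$gamma[gp, 2]) -
                        digamma(state$gamma[gp, 1] + state$gamma[gp, 2])
            dg <- 0
            for (i in seq_len(d))
                dg <- dg + digamma((state$v[g] + 1 - i) / 2)
            dev <- x[cc, ] - state$mu[g, ]
            quad <- as.numeric(t(dev) %*% solve(state$Psi[, , g]) %*% dev)
            term <- term + 0.5 * (dg + d * log(2) -
                log(det(state$Psi[, , g])) - d / state$kappa[g] -
                state$v[g] * quad)
            logu[g] <- term
        }
        u <- exp(logu - max(logu))
        r[cc, ] <- u / sum(u)
    }
    r
}

oracleGaussian <- function(x, mu, Sigma) {
    n <- length(mu)
    dev <- x - mu
    as.numeric(exp(-t(dev) %*% solve(Sigma) %*% dev / 2) /
        ((2 * pi)^(n / 2) * sqrt(det(Sigma))))
}

oracleCovEStep <- function(x, pi, mu, Sigma) {
    C <- nrow(x)
    G <- ncol(pi)
    r <- matrix(0, C, G)
    for (cc in seq_len(C)) {
        num <- numeric(G)
        for (g in seq_len(G))
            num[g] <- pi[cc, g] * oracleGaussian(x[cc, ], mu[[g]],
                Sigma[[g]])
        r[cc, ] <- num / sum(num)
    }
    r
}

oracleCovMStep <- function(r, x, p, W) {
    C <- nrow(x)
    G <- ncol(r)
    n <- ncol(x)
    pi <- matrix(0, C, G)
    mu <- vector("list", G)
    Sigma <- vector("list", G)
    for (cc in seq_len(C))
        for (g in seq_len(G))
            pi[cc, g] <- (r[cc, g] + W * p[cc, g]) / (1 + W)
    for (g in seq_len(G)) {
        N <- sum(r[, g])
        m <- rep(0, n)
        for (cc in seq_len(C)) m <- m + r[cc, g] * x[cc, ]
        mu[[g]] <- m / N
        S <- matrix(0, n, n)
        for (cc in seq_len(C)) {
            dev <- x[cc, ] - mu[[g]]
            S <- S + r[cc, g] * (dev %o% dev)
        }
        Sigma[[g]] <- S / N
    }
    list(pi = pi, mu = mu, Sigma = Sigma)
}

oracleCovObjective <- function(x, p, pi, mu, Sigma, W) {
    C <- nrow(x)
    G <- ncol(pi)
    ll <- 0
    for (cc in seq_len(C)) {
        s <- 0
        for (g in seq_len(G))
            s <- s + pi[cc, g] * oracleGaussian(x[cc, ], mu[[g]],
                Sigma[[g]])
        ll <- ll + log(s)
    }
    kl <- 0
    for (cc in seq_len(C))
        for (g in seq_len(G))
            if (p[cc, g] > 0)
                kl <- kl + p[cc, g] * log(p[cc, g] /
                    max(pi[cc, g], 1e-12))
    ll - W * kl
}

# brute-force genome-number rule over an explicit count multiset
bruteGenomeNumber <- function(counts) {
    vals <- sort(unique(counts))
    mult <- vapply(vals, function(v) sum(counts == v), numeric(1))
    gMode <- max(vals[mult == max(mult)])
    modeMult <- sum(counts == gMode)
    best <- -Inf
    for (v in vals)
        if (sum(counts == v) >= 0.5 * modeMult && v > best)
            best <- v
    list(G = as.integer(best), GMode = as.integer(gMode))
}

# all count multisets (non-decreasing sequences) of size <= maxSize with
# values in 1..maxVal
enumerateMultisets <- function(maxSize, maxVal) {
    out <- list()
    grow <- function(prefix, lo) {
        if (length(prefix) > 0)
            out[[length(out) + 1L]] <<- prefix
        if (length(prefix) == maxSize)
            return(invisible())
        for (v in lo:maxVal)
            grow(c(prefix, v), v)
    }
    grow(integer(), 1L)
    out
}

markerSetFromCounts <- function(counts) {
    groups <- lapply(seq_along(counts), function(i)
        sprintf("m%d_c%d", i, seq_len(counts[i])))
    names(groups) <- sprintf("m%d", seq_along(counts))
    new("MarkerSet", groups = groups)
}

# exhaustive minimum normalized cut over bipartitions of a small graph
bruteNormalizedCut <- function(M) {
    n <- nrow(M)
    best <- NULL
    bestVal <- Inf
    for (code in 1:(2^(n - 1) - 1)) {
        side <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
        a <- which(side == 0L)
        b <- which(side == 1L)
        cut <- sum(M[a, b])
        volA <- sum(M[a, ])
        volB <- sum(M[b, ])
        if (volA == 0 || volB == 0)
            next
        val <- cut * (1 / volA + 1 / volB)
        if (val < bestVal) {
            bestVal <- val
            best <- side
        }
    }
    list(side = best, value = bestVal)
}

# random mixture state for DPGMM oracle comparisons
randomDpgmmState <- function(C, d, G, seed) {
    set.seed(seed)
    x <- matrix(rnorm(C * d), C, d)
    w <- runif(C, 0.5, 2)
    r <- matrix(rgamma(C * G, 1), C, G)
    r <- r / rowSums(r)
    state <- list(G = G, d = d, alpha = 1, kappa0 = 1e-4,
        mu0 = colMeans(x), Psi0 = cov(x) + diag(0.1, d), v0 = d, r = r)
    list(state = state, x = x, w = w)
}

# tiny two-genome community for fast pipeline tests
smallCommunity <- function(seed, G = 2L, genomeBp = 1.2e6) {
    generateCommunity(communitySpec(G = G, genomeBp = genomeBp,
        markerCount = 20L, seed = seed))
}
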