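#' Second-layer KL-regularized Gaussian mixture over log coverages
#'
#' Sequencing depth reflects genome abundance, so contigs of one genome
#' share a per-sample mean depth; but positional depth is overdispersed
#' relative to Poisson, motivating a Gaussian model on log coverages.
#' Each component g (one per extended seed / genome) has mean mu_g and
#' covariance Sigma_g over the n samples, and -- unlike a plain GMM --
#' every contig carries its own prior pi_c over components. The objective
#' is
#' \deqn{\ell = \sum_c \log \sum_g \pi_c^g N(x_c | \mu^g, \Sigma^g)
#'   - W \sum_c KL(p_c \| \pi_c)}
#' where p_c is the composition classifier's probability row for contig c
#' and W > 0 (default 1/n) sets how strongly the prior is pulled toward
#' the composition evidence; with many samples the coverage term dominates.
#' EM updates: responsibilities r_c^g proportional to pi_c^g N(x_c);
#' pi_c^g = (r_c^g + W p_c^g) / (1 + W); mu and Sigma are the
#' responsibility-weighted mean and scatter.
#'
#' @name coverageModel
NULL

logGaussianDensities <- function(x, mu, Sigma) {
    C <- nrow(x)
    G <- length(mu)
    n <- ncol(x)
    out <- matrix(0, C, G)
    for (g in seq_len(G)) {
        ch <- safeChol(Sigma[[g]])
        logdet <- 2 * sum(log(diag(ch)))
        xc <- t(x) - mu[[g]]
        y <- backsolve(ch, xc, transpose = TRUE)
        out[, g] <- -0.5 * (n * log(2 * pi) + logdet + colSums(y^2))
    }
    out
}

#' @rdname coverageModel
#' @param x numeric matrix of log-transformed depths (contigs x samples).
#' @param pSvm probability matrix from \code{\link{predictPSvm}} (contigs
#'   x components), rows summing to 1.
#' @param pi prior matrix (contigs x components), rows summing to 1.
#' @param mu list of component mean vectors.
#' @param Sigma list of component covariance matrices.
#' @param W positive regularization weight.
#' @return \code{coverageObjective}: the scalar objective; zero-prior
#'   entries facing positive \code{pSvm} mass are floored at 1e-12 inside
#'   the KL term.
#' @export
coverageObjective <- function(x, pSvm, pi, mu, Sigma, W) {
    logdens <- logGaussianDensities(x, mu, Sigma)
    lw <- log(pmax(pi, 0)) + logdens   # -Inf where pi == 0
    ll <- sum(logRowSumExp(lw))
    piF <- pmax(pi, 1e-12)
    kl <- sum(ifelse(pSvm > 0, pSvm * log(pSvm / piF), 0))
    ll - W * kl
}

#' @rdname coverageModel
#' @return \code{covEStep}: the responsibility matrix r (rows sum to 1);
#'   an all-zero numerator row becomes uniform with a warning.
#' @export
covEStep <- function(x, pi, mu, Sigma) {
    logdens <- logGaussianDensities(x, mu, Sigma)
    lw <- log(pmax(pi, 0)) + logdens
    mx <- apply(lw, 1L, max)
    bad <- !is.finite(mx)
    if (any(bad)) {
        warning(sum(bad), " contig(s) with vanishing posterior mass; ",
            "uniform responsibilities assigned")
        lw[bad, ] <- 0
        mx[bad] <- 0
    }
    r <- exp(lw - mx)
    r / rowSums(r)
}

#' @rdname coverageModel
#' @param r responsibility matrix.
#' @param ridge diagonal regularization added to each covariance as
#'   \code{ridge * mean(diag(Sigma))} (variance floor 1e-6 when n = 1).
#' @return \code{covMStep}: list with updated \code{pi}, \code{mu},
#'   \code{Sigma} and \code{keep}, a logical vector marking components
#'   that retained responsibility mass (empty components are retired by
#'   the driver).
#' @export
covMStep <- function(r, x, pSvm, W, ridge = 1e-6) {
    Nk <- colSums(r)
    keep <- Nk >= 1e-8
    pi <- (r + W * pSvm) / (1 + W)
    n <- ncol(x)
    mu <- vector("list", ncol(r))
    Sigma <- vector("list", ncol(r))
    for (g in which(keep)) {
        mu[[g]] <- colSums(r[, g] * x) / Nk[g]
        xc <- sweep(x, 2L, mu[[g]])
        S <- crossprod(xc * r[, g], xc) / Nk[g]
        if (n == 1L)
            S[1L, 1L] <- max(S[1L, 1L], 1e-6)
        else
            S <- S + diag(ridge * mean(diag(S)) + 1e-12, n)
        Sigma[[g]] <- S
    }
    list(pi = pi, mu = mu, Sigma = Sigma, keep = keep)
}

#' Fit the coverage mixture by EM
#'
#' Initializes the contig-specific priors at the composition
#' probabilities (pi = pSvm) and the component moments from one M-step
#' with r = pSvm -- a warm start that avoids the local optima of random
#' initialization -- then alternates E- and M-steps until the objective
#' changes by less than \code{tol} (default 1e-4) or \code{maxIter}
#' iterations (default 200). The objective is non-decreasing along the
#' run (up to 1e-8 numerical slack). Components that lose all
#' responsibility mass are retired and the remaining columns
#' renormalized. Contigs are finally hard-assigned by maximum
#' responsibility.
#'
#' @inheritParams coverageObjective
#' @param W regularization weight; default 1/n (n = number of samples).
#' @param tol convergence tolerance on the objective change.
#' @param maxIter maximum EM iterations.
#' @return list with \code{assignment} (integer vector over the original
#'   component indices), \code{r}, \code{pi}, \code{mu}, \code{Sigma},
#'   \code{components} (original indices of surviving components) and
#'   \code{objective} (trace of the objective).
#' @export
runCoverageGmm <- function(x, pSvm, W = 1 / ncol(x), tol = 1e-4,
        maxIter = 200L) {
    x <- as.matrix(x)
    pSvm <- as.matrix(pSvm)
    stopifnot(nrow(x) == nrow(pSvm), W > 0)
    if (nrow(x) < ncol(pSvm))
        stop("need at least as many contigs as components")
    active <- seq_len(ncol(pSvm))
    p <- pSvm
    m <- covMStep(p, x, p, W)
    pi <- p
    mu <- m$mu
    Sigma <- m$Sigma
    if (!all(m$keep)) {
        sel <- which(m$keep)
        active <- active[sel]
        p <- p[, sel, drop = FALSE]
        p <- p / pmax(rowSums(p), 1e-12)
        pi <- pi[, sel, drop = FALSE]
        pi <- pi / pmax(rowSums(pi), 1e-12)
        mu <- mu[sel]
        Sigma <- Sigma[sel]
    }
    obj <- coverageObjective(x, p, pi, mu, Sigma, W)
    trace <- obj
    r <- NULL
    for (it in seq_len(maxIter)) {
        r <- covEStep(x, pi, mu, Sigma)
        m <- covMStep(r, x, p, W)
        if (!all(m$keep)) {
            sel <- which(m$keep)
            active <- active[sel]
            r <- r[, sel, drop = FALSE]
            r <- r / pmax(rowSums(r), 1e-12)
            p <- p[, sel, drop = FALSE]
            p <- p / pmax(rowSums(p), 1e-12)
            m <- covMStep(r, x, p, W)
        }
        pi <- m$pi
        mu <- m$mu
        Sigma <- m$Sigma
        newObj <- coverageObjective(x, p, pi, mu, Sigma, W)
        trace <- c(trace, newObj)
        if (abs(newObj - obj) < tol) {
            obj <- newObj
            break
        }
        obj <- newObj
    }
    if (is.null(r))
        r <- covEStep(x, pi, mu, Sigma)
    hard <- max.col(r, ties.method = "first")
    list(assignment = active[hard], r = r, pi = pi, mu = mu,
        Sigma = Sigma, components = active, objective = trace)
}
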