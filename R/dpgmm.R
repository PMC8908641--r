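#' First-layer weighted variational Dirichlet-process Gaussian mixture
#'
#' The first layer clusters contigs in the space of PCA-reduced canonical
#' k-mer frequencies concatenated with log coverages. The mixture is a
#' truncated stick-breaking Dirichlet-process Gaussian mixture with a
#' normal-inverse-Wishart base measure, fitted by mean-field variational
#' inference; every contig enters the sufficient statistics with weight
#' w_c = l_c / mean(l), so longer contigs dominate the parameter
#' estimates. Priors: concentration alpha = 1; mean precision
#' kappa = 1e-4 (nearly non-informative); mu_0 = mean of the features;
#' Psi = covariance of the features; degrees of freedom v = d.
#'
#' \code{initDpgmm} draws the initial responsibilities from a symmetric
#' Dirichlet(1) per contig under \code{seed} and applies one M-step so all
#' component fields are populated.
#'
#' @param x numeric feature matrix (contigs x d), e.g.
#'   \code{\link{featureMatrix}}.
#' @param w positive contig weights averaging 1.
#' @param GInit initial (truncation) number of components; the layer is
#'   started at 3 times the marker-estimated genome number.
#' @param seed integer seed for the responsibility initialization.
#' @param init \code{"kmeans"} (default) seeds the responsibilities from a
#'   k-means partition of the features, so components start on distinct
#'   regions of the data; \code{"random"} draws them from a symmetric
#'   Dirichlet(1) per contig. Variational fitting can empty components but
#'   never split one, so the k-means start avoids the local optimum where
#'   two nearby genomes share a component from the outset.
#' @return a state list with elements \code{G}, \code{gamma} (G x 2
#'   stick-breaking Beta parameters), \code{kappa}, \code{v} (length-G),
#'   \code{mu} (G x d posterior means), \code{Psi} (d x d x G scale
#'   matrices), \code{r} (contigs x G responsibilities) and the priors.
#' @name dpgmm
NULL

#' @rdname dpgmm
#' @export
initDpgmm <- function(x, w, GInit, seed = 1L,
        init = c("kmeans", "random")) {
    init <- match.arg(init)
    x <- as.matrix(x)
    C <- nrow(x)
    if (C < 2L)
        stop("at least 2 contigs are required")
    stopifnot(GInit >= 1L, length(w) == C, all(w > 0))
    G <- min(as.integer(GInit), C)
    d <- ncol(x)
    mu0 <- colMeans(x)
    Psi0 <- stats::cov(x)
    # guard rank deficiency of the empirical covariance prior
    Psi0 <- Psi0 + diag(1e-8 * (sum(diag(Psi0)) / d + 1), d)
    state <- list(
        G = G, d = d, alpha = 1, kappa0 = 1e-4, mu0 = mu0, Psi0 = Psi0,
        v0 = d)
    set.seed(seed)
    if (init == "kmeans" && G > 1L) {
        # standardize columns for the init only, so that the numerically
        # small composition PCs and the larger log depths weigh equally
        sds <- apply(x, 2L, stats::sd)
        xs <- sweep(x, 2L, colMeans(x)) %*% diag(1 / pmax(sds, 1e-12),
            ncol(x))
        km <- tryCatch(
            stats::kmeans(xs, centers = G, nstart = 5L, iter.max = 50L),
            error = function(e) NULL)
        if (is.null(km)) {
            # fewer distinct points than centers: fall back to random
            r <- matrix(stats::rgamma(C * G, shape = 1), C, G)
        } else {
            r <- matrix(0, C, G)
            r[cbind(seq_len(C), km$cluster)] <- 1
        }
    } else {
        r <- matrix(stats::rgamma(C * G, shape = 1), C, G)
    }
    state$r <- r / rowSums(r)
    mStepDpgmm(state, x, w)
}

#' @rdname dpgmm
#' @param state a DPGMM state list.
#' @details \code{mStepDpgmm} applies the variational updates of the
#' stick-breaking Beta parameters and the normal-inverse-Wishart fields
#' given the responsibilities: with N_g = sum_c w_c r_cg,
#' gamma_g1 = 1 + N_g; gamma_g2 = alpha + sum of N_g' over g' > g;
#' kappa_g = kappa + N_g; mu_g = (kappa mu_0 + sum_c w_c r_cg x_c) /
#' kappa_g; Psi_g = Psi + weighted scatter about the weighted mean
#' + (kappa N_g / kappa_g) (xbar_g - mu_0)(xbar_g - mu_0)^T;
#' v_g = v + N_g. Components with zero responsibility mass fall back to
#' the priors.
#' @export
mStepDpgmm <- function(state, x, w) {
    x <- as.matrix(x)
    r <- state$r
    G <- state$G
    d <- state$d
    rw <- r * w
    Nk <- colSums(rw)
    tail <- sum(Nk) - cumsum(Nk)
    state$gamma <- cbind(1 + Nk, state$alpha + tail)
    state$kappa <- state$kappa0 + Nk
    state$v <- state$v0 + Nk
    sumx <- crossprod(rw, x)                       # G x d
    state$mu <- (matrix(state$kappa0 * state$mu0, G, d, byrow = TRUE) +
        sumx) / state$kappa
    Psi <- array(0, c(d, d, G))
    for (g in seq_len(G)) {
        if (Nk[g] < 1e-12) {
            state$gamma[g, 1L] <- 1
            state$kappa[g] <- state$kappa0
            state$v[g] <- state$v0
            state$mu[g, ] <- state$mu0
            Psi[, , g] <- state$Psi0
            next
        }
        xbar <- sumx[g, ] / Nk[g]
        xc <- sweep(x, 2L, xbar)
        S <- crossprod(xc * rw[, g], xc)
        dev <- xbar - state$mu0
        Psi[, , g] <- state$Psi0 + S +
            (state$kappa0 * Nk[g] / state$kappa[g]) * tcrossprod(dev)
    }
    state$Psi <- Psi
    state
}

#' @rdname dpgmm
#' @details \code{eStepDpgmm} recomputes the responsibilities: the
#' unnormalized log responsibility of contig c in component g is the
#' expected log stick weight (digamma terms of the Beta parameters) plus
#' half of [sum_i digamma((v_g + 1 - i)/2) + d ln 2 - ln|Psi_g| -
#' d/kappa_g - v_g (x_c - mu_g)^T Psi_g^{-1} (x_c - mu_g)]; rows are
#' normalized in log space.
#' @export
eStepDpgmm <- function(state, x) {
    x <- as.matrix(x)
    C <- nrow(x)
    G <- state$G
    d <- state$d
    g1 <- state$gamma[, 1L]
    g2 <- state$gamma[, 2L]
    eLogBeta <- digamma(g1) - digamma(g1 + g2)
    eLog1mBeta <- digamma(g2) - digamma(g1 + g2)
    stickTerm <- eLogBeta + c(0, cumsum(eLog1mBeta))[seq_len(G)]
    logr <- matrix(0, C, G)
    for (g in seq_len(G)) {
        ch <- safeChol(state$Psi[, , g])
        logdet <- 2 * sum(log(diag(ch)))
        xc <- t(x) - state$mu[g, ]
        y <- backsolve(ch, xc, transpose = TRUE)
        quad <- colSums(y^2)
        logr[, g] <- stickTerm[g] + 0.5 * (
            sum(digamma((state$v[g] + 1 - seq_len(d)) / 2)) +
            d * log(2) - logdet - d / state$kappa[g] -
            state$v[g] * quad)
    }
    state$r <- exp(logr - logRowSumExp(logr))
    state$r <- state$r / rowSums(state$r)
    state
}

#' @rdname dpgmm
#' @param lengths contig lengths in bp.
#' @param minComponentBp components whose hard-assigned contigs total less
#'   than this many bp are dissolved (default 500 kb).
#' @details \code{dissolveSmallComponents} keeps the integrity of genome-
#' sized components: any component whose argmax-assigned contigs total
#' fewer than \code{minComponentBp} base pairs is removed and the
#' responsibilities of every contig are renormalized over the surviving
#' components. If every component is under the threshold the largest one
#' is kept.
#' @export
dissolveSmallComponents <- function(state, lengths, minComponentBp = 5e5) {
    bp <- hardComponentBp(state, lengths)
    keep <- bp >= minComponentBp
    if (!any(keep)) {
        warning("all components below ", minComponentBp,
            " bp; keeping the largest")
        keep[which.max(bp)] <- TRUE
    }
    if (all(keep))
        return(state)
    dropComponents(state, which(!keep))
}

hardComponentBp <- function(state, lengths) {
    hard <- max.col(state$r, ties.method = "first")
    vapply(seq_len(state$G), function(g) sum(lengths[hard == g]),
        numeric(1))
}

# remove a set of components, renormalizing responsibilities over the rest
dropComponents <- function(state, drop) {
    keep <- setdiff(seq_len(state$G), drop)
    r <- state$r[, keep, drop = FALSE]
    rs <- rowSums(r)
    zero <- rs <= 0
    if (any(zero)) {
        r[zero, ] <- 1 / ncol(r)
        rs[zero] <- 1
    }
    state$r <- r / rs
    state$G <- length(keep)
    state$gamma <- state$gamma[keep, , drop = FALSE]
    state$kappa <- state$kappa[keep]
    state$v <- state$v[keep]
    state$mu <- state$mu[keep, , drop = FALSE]
    state$Psi <- state$Psi[, , keep, drop = FALSE]
    state
}

#' Run the first clustering layer
#'
#' Alternates E- and M-steps of the weighted variational DP Gaussian
#' mixture, dissolving under-sized components every
#' \code{dissolveEvery} iterations, until the mean absolute responsibility
#' change drops below \code{tol} or \code{maxIter} is reached. Contigs are
#' then hard-assigned by maximum responsibility, and each resulting
#' cluster is screened for compositional heterogeneity: clusters whose
#' average pairwise Euclidean distance between raw k-mer frequency
#' profiles exceeds \code{maxDistance} are flagged abnormal and excluded
#' from further processing.
#'
#' @inheritParams initDpgmm
#' @param lengths contig lengths (bp), used for dissolution.
#' @param kmerProfiles optional raw k-mer frequency matrix (contigs x D)
#'   for abnormal screening; \code{NULL} disables the screen.
#' @param maxDistance abnormality cutoff on the average pairwise profile
#'   distance (default 0.04).
#' @param minComponentBp dissolution threshold in bp (default 500 kb).
#' @param tol convergence tolerance on mean |delta r| (default 1e-3).
#' @param maxIter maximum number of iterations (default 300).
#' @param dissolveEvery dissolution period in iterations (default 10).
#' @return list with \code{clusters} (a list, each with \code{members} =
#'   integer row indices, \code{abnormal} flag and \code{avgDistance}),
#'   \code{assignment} (integer vector) and the final \code{state}.
#' @export
runFirstLayer <- function(x, w, lengths, GInit, kmerProfiles = NULL,
        maxDistance = 0.04, minComponentBp = 5e5, tol = 1e-3,
        maxIter = 300L, dissolveEvery = 10L, seed = 1L,
        init = c("kmeans", "random")) {
    x <- as.matrix(x)
    state <- initDpgmm(x, w, GInit, seed = seed, init = init)
    rPrev <- state$r
    for (it in seq_len(maxIter)) {
        state <- eStepDpgmm(state, x)
        state <- mStepDpgmm(state, x, w)
        if (it %% dissolveEvery == 0L && state$G > 1L) {
            # dissolve empty components freely, but under-sized occupied
            # components only one per checkpoint: their contigs re-home
            # to the nearest surviving component and the fit re-converges
            # before the next removal, which keeps a temporarily split
            # genome from being absorbed elsewhere wholesale
            bp <- hardComponentBp(state, lengths)
            if (any(bp >= minComponentBp) && any(bp < minComponentBp)) {
                drop <- which(bp == 0)
                small <- which(bp > 0 & bp < minComponentBp)
                if (length(small))
                    drop <- c(drop, small[which.min(bp[small])])
                state <- dropComponents(state, drop)
                state <- mStepDpgmm(state, x, w)
            }
        }
        converged <- ncol(state$r) == ncol(rPrev) &&
            mean(abs(state$r - rPrev)) < tol
        bp <- hardComponentBp(state, lengths)
        prunable <- state$G > 1L && any(bp >= minComponentBp) &&
            any(bp < minComponentBp)
        if (converged && !prunable)
            break
        rPrev <- state$r
    }
    # safety nets: prune components the iteration budget left behind; if
    # nothing at all reached the threshold (a pool smaller than one
    # genome-sized component), collapse to the largest so the pool is
    # handed to the second layer as one cluster
    bp <- hardComponentBp(state, lengths)
    if (any(bp < minComponentBp) && state$G > 1L)
        state <- dissolveSmallComponents(state, lengths, minComponentBp)
    assignment <- max.col(state$r, ties.method = "first")
    clusters <- lapply(sort(unique(assignment)), function(g) {
        members <- which(assignment == g)
        avgDist <- if (is.null(kmerProfiles)) 0 else
            averagePairwiseDistance(
                kmerProfiles[members, , drop = FALSE])
        list(members = members,
            abnormal = !is.null(kmerProfiles) && avgDist > maxDistance,
            avgDistance = avgDist)
    })
    list(clusters = clusters, assignment = assignment, state = state)
}
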