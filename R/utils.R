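# deterministic child-seed derivation: all stochastic steps draw their own
# seed from the master seed so that insertion/removal of one step does not
# shift the stream of another
childSeed <- function(seed, index) {
    as.integer((as.numeric(seed) %% 2147483647 * 1009 +
        as.numeric(index) * 9973) %% 2147483646 + 1)
}

logRowSumExp <- function(m) {
    mx <- apply(m, 1L, max)
    mx[!is.finite(mx)] <- 0
    mx + log(rowSums(exp(m - mx)))
}

# Cholesky with a diagonal ridge retried on failure; returns the upper factor
safeChol <- function(sigma, ridge = 1e-6) {
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) {
        d <- nrow(sigma)
        ch <- chol(sigma + diag(ridge * sum(diag(sigma)) / d + 1e-12, d))
    }
    ch
}

vlog <- function(verbose, fmt, ...) {
    if (isTRUE(verbose))
        message(sprintf(fmt, ...))
    invisible(NULL)
}
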