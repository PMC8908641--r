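#' Train the semi-supervised composition classifier on extended seeds
#'
#' From each extended seed, \code{subseedsPerSeed} sub-seeds of
#' \code{lenRange} bp (default 300 of 3--4 kb) are randomly sampled; a
#' multi-class SVM with RBF kernel is trained on their canonical k-mer
#' frequencies with the seed as label. The kernel width is fixed at
#' gamma = 1 / (number of distinct canonical k-mers), i.e. 1/136 for
#' tetramers; the cost parameter is left at C = 1. Features are
#' column-standardized inside the fit (the library default; raw frequency
#' columns are so small that decision values degenerate and probability
#' calibration collapses without it). Class probabilities use libsvm's
#' pairwise-coupling calibration, whose internal cross-validation draws
#' from the R RNG, so the fit is reproducible under \code{seed}.
#'
#' @param seeds a \code{DNAStringSet} of extended seeds (>= 1).
#' @param k k-mer size (default 4).
#' @param subseedsPerSeed training fragments per seed (default 300).
#' @param lenRange fragment length bounds in bp (default 3000--4000).
#' @param seed integer seed.
#' @return a fitted model object (list) for \code{\link{predictPSvm}}.
#' @export
trainKmerModel <- function(seeds, k = 4L, subseedsPerSeed = 300L,
        lenRange = c(3000L, 4000L), seed = 1L) {
    stopifnot(length(seeds) >= 1L)
    idx <- canonicalKmerIndex(k)
    labels <- names(seeds)
    if (length(seeds) == 1L)
        return(structure(list(trivial = TRUE, labels = labels, k = k,
            index = idx), class = "kmerModel"))
    set.seed(seed)
    frags <- lapply(seq_along(seeds), function(i)
        sampleFragments(seeds[[i]], subseedsPerSeed, lenRange[1L],
            lenRange[2L]))
    x <- kmerFrequencies(do.call(c, frags), k = k, index = idx)
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    y <- factor(rep(labels, each = subseedsPerSeed), levels = labels)
    fit <- e1071::svm(x, y, kernel = "radial",
        gamma = 1 / attr(idx, "D"), cost = 1, probability = TRUE,
        scale = apply(x, 2L, stats::var) > 0)
    structure(list(trivial = FALSE, fit = fit, labels = labels, k = k,
        index = idx), class = "kmerModel")
}

#' Predict per-seed membership probabilities for contigs
#'
#' Applies the fitted composition classifier to the full-length canonical
#' k-mer frequency profile of each contig, returning the calibrated
#' probability that the contig belongs to each seed's genome. Rows sum
#' to 1; a contig with no valid k-mer window gets a uniform row.
#'
#' @param model a model from \code{\link{trainKmerModel}}.
#' @param contigs a named \code{DNAStringSet}.
#' @return numeric matrix (contigs x seeds), rownames = contig ids,
#'   colnames = seed labels, rows summing to 1.
#' @export
predictPSvm <- function(model, contigs) {
    stopifnot(inherits(model, "kmerModel"))
    ids <- names(contigs)
    G <- length(model$labels)
    if (model$trivial) {
        p <- matrix(1, length(contigs), 1L,
            dimnames = list(ids, model$labels))
        return(p)
    }
    x <- kmerFrequencies(contigs, k = model$k, index = model$index)
    empty <- rowSums(x) == 0
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    pr <- stats::predict(model$fit, x, probability = TRUE)
    p <- attr(pr, "probabilities")[, model$labels, drop = FALSE]
    if (any(empty)) {
        warning(sum(empty), " contig(s) with no valid k-mer window; ",
            "uniform probabilities assigned")
        p[empty, ] <- 1 / G
    }
    p <- p / rowSums(p)
    rownames(p) <- ids
    p
}
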