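#' Select marker-sharing contig groups for seed construction
#'
#' Contigs carrying the same single-copy marker gene must come from
#' different genomes. Every marker mapped to at least \code{GMode} contigs
#' contributes its contig set as one group; the collection of groups is
#' the raw material for the seed-selection classifier.
#'
#' @param markers a \code{MarkerSet}.
#' @param GMode the mode of the per-marker contig counts (from
#'   \code{\link{estimateGenomeNumber}}).
#' @return named list of character vectors (marker id -> contig ids).
#' @export
selectGroups <- function(markers, GMode) {
    g <- markerGroups(markers)
    if (length(g) == 0L)
        stop("empty marker set: no groups to select")
    sel <- g[vapply(g, length, integer(1)) >= GMode]
    if (length(sel) == 0L)
        stop("no marker group with at least GMode = ", GMode, " contigs")
    sel
}

#' Accumulate cross-prediction bonuses into an adjacency matrix
#'
#' Scoring rule shared by \code{\link{buildAdjacency}}: for a classifier
#' trained on group g_i (labels = its contig ids), every contig j in a
#' predicted group g_j whose predicted label f(j) = i adds
#' 1 / (number of contigs k in g_j with f(k) = i) to A[i, j]. When the
#' label i claims exactly one contig of g_j the bonus is 1; when it claims
#' two, each gets 0.5 because the tie cannot be resolved; labels claiming
#' no contig contribute nothing.
#'
#' @param A square numeric matrix with contig-id dimnames (modified and
#'   returned).
#' @param groups list of predicted groups (character vectors of contig
#'   ids).
#' @param predicted named character vector: predicted label (a training
#'   contig id) for every contig in the union of \code{groups}.
#' @return the updated matrix.
#' @export
accumulateBonuses <- function(A, groups, predicted) {
    for (gj in groups) {
        labs <- predicted[gj]
        cnt <- table(labs)
        for (j in gj) {
            i <- labs[[j]]
            A[i, j] <- A[i, j] + 1 / cnt[[i]]
        }
    }
    A
}

#' Build the contig adjacency matrix by classifier cross-prediction
#'
#' For each marker-sharing group with at least two contigs, a multi-class
#' SVM is trained on 20 random sub-contigs (1.5--2.5 kb) per member
#' contig, with the contig id as label and features combining the canonical
#' k-mer frequencies of the fragment with the parent contig's log
#' coverages. All contigs appearing in any group are then predicted with
#' their full-length features, and \code{\link{accumulateBonuses}} turns
#' the predictions into adjacency weight: entry A[i, j] accumulates
#' evidence that contigs i and j derive from the same genome.
#'
#' @param groups list of contig-id groups (from \code{\link{selectGroups}}).
#' @param contigs named \code{DNAStringSet} containing all grouped contigs.
#' @param logCov numeric matrix of log-transformed depths with contig
#'   rownames.
#' @param k k-mer size.
#' @param fragsPerContig training fragments per contig (default 20).
#' @param fragRange fragment length bounds in bp (default 1500--2500).
#' @param seed integer seed (fragment sampling).
#' @return square numeric matrix A indexed by the union of grouped
#'   contigs.
#' @export
buildAdjacency <- function(groups, contigs, logCov, k = 4L,
        fragsPerContig = 20L, fragRange = c(1500L, 2500L), seed = 1L) {
    stopifnot(length(groups) >= 1L)
    ids <- sort(unique(unlist(groups, use.names = FALSE)))
    idx <- canonicalKmerIndex(k)
    fullKmer <- kmerFrequencies(contigs[ids], k = k, index = idx)
    fullX <- cbind(fullKmer, logCov[ids, , drop = FALSE])
    colnames(fullX) <- paste0("f", seq_len(ncol(fullX)))
    A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (s in seq_along(groups)) {
        gi <- groups[[s]]
        if (length(gi) < 2L)
            next  # degenerate one-class trainer
        set.seed(childSeed(seed, s))
        frags <- lapply(gi, function(cid)
            sampleFragments(contigs[[cid]], fragsPerContig,
                fragRange[1L], fragRange[2L]))
        fragSeqs <- do.call(c, frags)
        trainKmer <- kmerFrequencies(fragSeqs, k = k, index = idx)
        parent <- rep(gi, each = fragsPerContig)
        trainX <- cbind(trainKmer, logCov[parent, , drop = FALSE])
        colnames(trainX) <- colnames(fullX)
        fit <- e1071::svm(trainX, factor(parent, levels = gi),
            kernel = "radial", cost = 1,
            scale = apply(trainX, 2L, stats::var) > 0)
        pred <- as.character(stats::predict(fit, fullX))
        names(pred) <- ids
        A <- accumulateBonuses(A, groups, pred)
    }
    A
}

#' Spectral clustering of the symmetrized adjacency matrix
#'
#' Clusters the contig graph M = A + t(A) into \code{G} groups with
#' normalized-Laplacian spectral clustering: the rows of the G
#' eigenvectors of L_sym = I - D^{-1/2} M D^{-1/2} with smallest
#' eigenvalues are row-normalized and partitioned by k-means (10 restarts
#' under \code{seed}). Isolated nodes keep zero embedding rows and land
#' wherever k-means places them.
#'
#' @param A square adjacency matrix with contig-id dimnames.
#' @param G number of clusters (clamped to the node count).
#' @param seed integer seed for k-means.
#' @param nstart k-means restarts.
#' @return named integer vector of cluster labels (1..G).
#' @export
spectralSeedClusters <- function(A, G, seed = 1L, nstart = 10L) {
    stopifnot(nrow(A) == ncol(A), G >= 1L)
    n <- nrow(A)
    G <- min(as.integer(G), n)
    if (G == 1L)
        return(stats::setNames(rep(1L, n), rownames(A)))
    M <- A + t(A)
    deg <- rowSums(M)
    dhalf <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    L <- diag(n) - (dhalf %o% dhalf) * M
    eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
    U <- eig$vectors[, n:(n - G + 1L), drop = FALSE]
    norms <- sqrt(rowSums(U^2))
    U <- U / ifelse(norms > 0, norms, 1)
    set.seed(seed)
    km <- tryCatch(
        stats::kmeans(U, centers = G, nstart = nstart, iter.max = 100L),
        error = function(e) NULL)
    labels <- if (is.null(km)) {
        # fewer distinct embedding rows than G: fall back to hierarchical
        stats::cutree(stats::hclust(stats::dist(U), method = "average"),
            k = G)
    } else km$cluster
    stats::setNames(as.integer(labels), rownames(A))
}

#' Concatenate spectral clusters into extended seeds
#'
#' Contigs in each spectral cluster are concatenated (input contig order)
#' into one extended seed sequence, the labeled training material for the
#' composition classifier. Empty clusters are dropped.
#'
#' @param partition named integer vector (contig id -> cluster label).
#' @param contigs named \code{DNAStringSet}.
#' @return a \code{DNAStringSet} of seeds named \code{seed_1}, ...; the
#'   member contig ids are kept in the \code{members} metadata column.
#' @export
buildSeeds <- function(partition, contigs) {
    labels <- sort(unique(partition))
    memberLists <- lapply(labels, function(lb) {
        ids <- names(partition)[partition == lb]
        ids[order(match(ids, names(contigs)))]
    })
    memberLists <- memberLists[lengths(memberLists) > 0L]
    seqs <- Biostrings::DNAStringSet(vapply(memberLists, function(ids)
        paste(as.character(contigs[ids]), collapse = ""), character(1)))
    names(seqs) <- paste0("seed_", seq_along(memberLists))
    S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
        members = I(memberLists))
    seqs
}
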