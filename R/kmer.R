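#' Canonical k-mer index
#'
#' Because sequencing reads come from either strand, a k-mer and its
#' reverse complement are counted as one ("canonical") k-mer: each of the
#' 4^k words maps to the lexicographically smaller of itself and its
#' reverse complement. For k = 4 this yields 136 distinct canonical
#' tetramers.
#'
#' @param k k-mer size (>= 1).
#' @return an integer vector of length 4^k, named by k-mer (alphabetical
#'   order, matching \code{\link[Biostrings]{oligonucleotideFrequency}}
#'   columns), giving the canonical column index of each k-mer. The number
#'   of canonical k-mers is \code{attr(x, "D")} and the canonical words in
#'   column order are \code{attr(x, "kmers")}.
#' @examples
#' idx <- canonicalKmerIndex(4)
#' attr(idx, "D")  # 136
#' @export
canonicalKmerIndex <- function(k) {
    stopifnot(k >= 1L)
    kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
    canon <- ifelse(kmers <= rc, kmers, rc)
    levels <- sort(unique(canon))
    idx <- match(canon, levels)
    names(idx) <- kmers
    attr(idx, "D") <- length(levels)
    attr(idx, "kmers") <- levels
    idx
}

#' Canonical k-mer frequency profiles
#'
#' Slides a width-k window with step 1 over each sequence; windows
#' containing a non-ACGT character are skipped; counts are accumulated on
#' canonical (strand-merged) k-mers and normalized to sum to 1 per
#' sequence. A sequence with no valid window yields an all-zero row (with a
#' warning), which downstream code treats as uninformative.
#'
#' @param seqs a \code{DNAStringSet}, \code{DNAString} or character vector.
#' @param k k-mer size; the binner's signature uses tetramers (k = 4).
#' @param index optional precomputed \code{\link{canonicalKmerIndex}(k)}.
#' @return numeric matrix, one row per sequence, one column per canonical
#'   k-mer (named), rows summing to 1 (or 0 for flagged rows).
#' @export
kmerFrequencies <- function(seqs, k = 4L, index = NULL) {
    if (is.character(seqs) || is(seqs, "DNAString"))
        seqs <- Biostrings::DNAStringSet(seqs)
    if (is.null(index))
        index <- canonicalKmerIndex(k)
    counts <- Biostrings::oligonucleotideFrequency(seqs, width = k)
    if (is.null(dim(counts)))
        counts <- matrix(counts, nrow = 1L, dimnames = list(NULL,
            names(counts)))
    canon <- t(rowsum(t(counts), group = index[colnames(counts)]))
    colnames(canon) <- attr(index, "kmers")
    tot <- rowSums(canon)
    if (any(tot == 0))
        warning(sum(tot == 0), " sequence(s) with no valid k-mer window; ",
            "all-zero profile returned")
    freq <- canon / ifelse(tot > 0, tot, 1)
    rownames(freq) <- names(seqs)
    freq
}

#' Average pairwise Euclidean distance between k-mer profiles
#'
#' Screening statistic for compositional heterogeneity of a cluster: the
#' mean over all unordered pairs of rows of the Euclidean distance between
#' raw canonical k-mer frequency vectors. First-layer clusters whose value
#' exceeds the cutoff (0.04 by default) are flagged abnormal.
#'
#' @param profiles numeric matrix of k-mer frequency rows.
#' @return the mean pairwise distance; 0 when there are fewer than 2 rows.
#' @export
averagePairwiseDistance <- function(profiles) {
    if (is.null(dim(profiles)) || nrow(profiles) <= 1L)
        return(0)
    mean(stats::dist(profiles))
}
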