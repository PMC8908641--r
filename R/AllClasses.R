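#' @import methods
NULL

#' ContigFeatures: per-contig feature container
#'
#' Holds, for a set of assembly contigs, the canonical k-mer frequency
#' profiles, their PCA-reduced representation, the per-sample mean depths,
#' contig lengths and the length-derived mixture weights. The matrix handed
#' to the first clustering layer is the row-wise concatenation of the
#' reduced composition and the log-transformed depths (see
#' \code{\link{featureMatrix}}).
#'
#' @slot contigIds character vector of unique contig identifiers.
#' @slot lengths numeric vector of contig lengths in bp.
#' @slot weights numeric vector of contig weights, length / mean(length);
#'   averages to 1 over the assembly.
#' @slot kmerFreq numeric matrix, one row per contig, one column per
#'   canonical k-mer, rows summing to 1 (or all-zero when a contig has no
#'   valid k-mer window).
#' @slot reduced numeric matrix of principal-component scores of
#'   \code{kmerFreq}.
#' @slot coverage numeric matrix of per-sample mean depths (one column per
#'   sequencing sample).
#' @slot k integer k-mer size.
#'
#' @seealso \code{\link{contigFeatures}} for the constructor.
#' @export
setClass("ContigFeatures",
    slots = c(
        contigIds = "character",
        lengths = "numeric",
        weights = "numeric",
        kmerFreq = "matrix",
        reduced = "matrix",
        coverage = "matrix",
        k = "integer"
    )
)

setValidity("ContigFeatures", function(object) {
    n <- length(object@contigIds)
    msg <- character()
    if (anyDuplicated(object@contigIds))
        msg <- c(msg, "contig ids must be unique")
    if (length(object@lengths) != n || length(object@weights) != n)
        msg <- c(msg, "lengths and weights must match the number of contigs")
    for (nm in c("kmerFreq", "reduced", "coverage")) {
        if (nrow(slot(object, nm)) != n)
            msg <- c(msg, sprintf("%s must have one row per contig", nm))
    }
    if (n > 0L) {
        if (any(object@weights <= 0))
            msg <- c(msg, "weights must be positive")
        if (abs(mean(object@weights) - 1) > 1e-8)
            msg <- c(msg, "weights must average to 1")
        if (any(object@coverage < 0))
            msg <- c(msg, "depths must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' MarkerSet: filtered single-copy marker-gene incidence
#'
#' Maps each single-copy marker gene to the set of contigs carrying a valid
#' hit. Because the markers are (nearly) single-copy per genome, the number
#' of contigs a marker maps to estimates the number of genomes present; the
#' multiset of these counts drives both genome-number estimation and seed
#' selection.
#'
#' @slot groups named list; element \code{m} is the character vector of
#'   contig ids carrying marker \code{m} (each contig at most once).
#'
#' @seealso \code{\link{filterMarkerHits}}, \code{\link{estimateGenomeNumber}}
#' @export
setClass("MarkerSet", slots = c(groups = "list"))

setValidity("MarkerSet", function(object) {
    g <- object@groups
    msg <- character()
    if (length(g)) {
        if (is.null(names(g)) || any(names(g) == "") || anyDuplicated(names(g)))
            msg <- c(msg, "groups must be uniquely named by marker id")
        if (!all(vapply(g, is.character, logical(1))))
            msg <- c(msg, "each group must be a character vector of contig ids")
        if (any(vapply(g, length, integer(1)) == 0L))
            msg <- c(msg, "groups must be non-empty")
        if (any(vapply(g, anyDuplicated, integer(1)) > 0L))
            msg <- c(msg, "a contig may appear at most once per marker")
    }
    if (length(msg)) msg else TRUE
})

#' BinningResult: final contig-to-bin assignment
#'
#' Partition of the (length-filtered) input contigs produced by
#' \code{\link{binContigs}}. Every contig appears exactly once, with status
#' \code{"output"} (member of an emitted bin), \code{"abnormal"}
#' (member of a compositionally heterogeneous first-layer cluster, removed
#' from further processing) or \code{"unclustered"}.
#'
#' @slot membership data.frame with columns \code{contig_id},
#'   \code{cluster_id}, \code{status}.
#' @slot clusters data.frame with one row per cluster: \code{cluster_id},
#'   \code{n_contigs}, \code{total_bp}, \code{estimated_G}, \code{status}.
#' @export
setClass("BinningResult",
    slots = c(membership = "data.frame", clusters = "data.frame"))

setValidity("BinningResult", function(object) {
    msg <- character()
    m <- object@membership
    if (!all(c("contig_id", "cluster_id", "status") %in% names(m)))
        msg <- c(msg, "membership needs contig_id, cluster_id, status columns")
    else {
        if (anyDuplicated(m$contig_id))
            msg <- c(msg, "each contig must appear exactly once")
        if (!all(m$status %in% c("output", "abnormal", "unclustered")))
            msg <- c(msg, "unknown status value")
    }
    if (length(msg)) msg else TRUE
})
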