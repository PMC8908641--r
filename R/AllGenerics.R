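#' @rdname ContigFeatures-class
#' @param x a \code{ContigFeatures}, \code{MarkerSet} or
#'   \code{BinningResult} object, as appropriate.
#' @export
setGeneric("contigIds", function(x) standardGeneric("contigIds"))

#' @rdname ContigFeatures-class
#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))

#' @rdname ContigFeatures-class
#' @export
setGeneric("contigWeights", function(x) standardGeneric("contigWeights"))

#' @rdname ContigFeatures-class
#' @export
setGeneric("kmerFreq", function(x) standardGeneric("kmerFreq"))

#' @rdname ContigFeatures-class
#' @export
setGeneric("coverageMatrix", function(x) standardGeneric("coverageMatrix"))

#' @rdname ContigFeatures-class
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname MarkerSet-class
#' @param x object.
#' @export
setGeneric("markerGroups", function(x) standardGeneric("markerGroups"))

#' @rdname MarkerSet-class
#' @export
setGeneric("markerCounts", function(x) standardGeneric("markerCounts"))

#' @rdname BinningResult-class
#' @param x object.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname BinningResult-class
#' @export
setGeneric("clusterSummary", function(x) standardGeneric("clusterSummary"))

setMethod("contigIds", "ContigFeatures", function(x) x@contigIds)
setMethod("contigLengths", "ContigFeatures", function(x) x@lengths)
setMethod("contigWeights", "ContigFeatures", function(x) x@weights)
setMethod("kmerFreq", "ContigFeatures", function(x) x@kmerFreq)
setMethod("coverageMatrix", "ContigFeatures", function(x) x@coverage)

#' @describeIn ContigFeatures-class feature matrix passed to the first
#'   layer: PCA-reduced composition concatenated with log(depth + 1).
setMethod("featureMatrix", "ContigFeatures", function(x) {
    m <- cbind(x@reduced, log(x@coverage + 1))
    rownames(m) <- x@contigIds
    m
})

setMethod("markerGroups", "MarkerSet", function(x) x@groups)

#' @describeIn MarkerSet-class number of contigs each marker maps to.
setMethod("markerCounts", "MarkerSet", function(x)
    vapply(x@groups, length, integer(1)))

setMethod("contigIds", "MarkerSet", function(x)
    sort(unique(unlist(x@groups, use.names = FALSE))))

setMethod("membership", "BinningResult", function(x) x@membership)
setMethod("clusterSummary", "BinningResult", function(x) x@clusters)
setMethod("contigIds", "BinningResult", function(x) x@membership$contig_id)

setMethod("show", "ContigFeatures", function(object) {
    cat(sprintf(
        "ContigFeatures: %d contigs, k = %d (%d canonical k-mers, %d PCs), %d sample(s)\n",
        length(object@contigIds), object@k, ncol(object@kmerFreq),
        ncol(object@reduced), ncol(object@coverage)))
    cat(sprintf("  total length: %.2f Mb\n", sum(object@lengths) / 1e6))
})

setMethod("show", "MarkerSet", function(object) {
    cnt <- markerCounts(object)
    cat(sprintf("MarkerSet: %d markers over %d contigs\n",
        length(cnt), length(contigIds(object))))
    if (length(cnt))
        cat("  contigs per marker:",
            paste(names(table(cnt)), table(cnt), sep = "x", collapse = ", "),
            "\n")
})

setMethod("show", "BinningResult", function(object) {
    m <- object@membership
    cl <- object@clusters
    out <- cl[cl$status == "output", , drop = FALSE]
    cat(sprintf("BinningResult: %d contigs -> %d bins\n", nrow(m), nrow(out)))
    for (s in c("output", "abnormal", "unclustered")) {
        n <- sum(m$status == s)
        if (n)
            cat(sprintf("  %-11s %5d contigs\n", s, n))
    }
    if (nrow(out))
        cat(sprintf("  bin sizes (Mb): %s\n",
            paste(sprintf("%.2f", sort(out$total_bp, decreasing = TRUE) / 1e6),
                collapse = ", ")))
})
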