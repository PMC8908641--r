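#' Read a marker-hit table
#'
#' Tab-delimited table of single-copy marker-gene hits on contigs, as
#' produced by upstream gene prediction plus HMM search: columns
#' marker_id, contig_id, coverage (fraction of the marker model covered by
#' the hit) and accuracy (fraction, as reported by the search). A header
#' row is optional and detected by non-numeric values in columns 3--4.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{marker_id}, \code{contig_id},
#'   \code{coverage}, \code{accuracy}.
#' @export
readMarkerHits <- function(path) {
    first <- utils::read.delim(path, header = FALSE, sep = "\t",
        nrows = 1L, stringsAsFactors = FALSE)
    if (ncol(first) < 4L)
        stop("marker-hit table needs 4 columns: ",
            "marker_id, contig_id, coverage, accuracy")
    hasHeader <- is.na(suppressWarnings(as.numeric(first[[3L]]))) ||
        is.na(suppressWarnings(as.numeric(first[[4L]])))
    df <- utils::read.delim(path, header = hasHeader, sep = "\t",
        stringsAsFactors = FALSE)
    df <- df[, 1:4]
    names(df) <- c("marker_id", "contig_id", "coverage", "accuracy")
    df$marker_id <- as.character(df$marker_id)
    df$contig_id <- as.character(df$contig_id)
    df$coverage <- as.numeric(df$coverage)
    df$accuracy <- as.numeric(df$accuracy)
    bad <- !is.finite(df$coverage) | !is.finite(df$accuracy) |
        df$coverage < 0 | df$coverage > 1 |
        df$accuracy < 0 | df$accuracy > 1
    if (any(bad))
        stop("marker-hit fractions must lie in [0,1]; offending rows: ",
            paste(utils::head(which(bad), 5L), collapse = ", "))
    df
}

#' Filter marker hits and build the marker-to-contig map
#'
#' Keeps hits with coverage >= \code{minCoverage} and accuracy >=
#' \code{minAccuracy} (both inclusive; defaults 0.5 and 0.6), then collects
#' for each marker the set of distinct contigs it maps to. A marker hitting
#' the same contig twice counts that contig once.
#'
#' @param hits data.frame as returned by \code{\link{readMarkerHits}}.
#' @param minCoverage,minAccuracy validity thresholds.
#' @return a \code{\link{MarkerSet}}; may be empty.
#' @export
filterMarkerHits <- function(hits, minCoverage = 0.5, minAccuracy = 0.6) {
    keep <- hits$coverage >= minCoverage & hits$accuracy >= minAccuracy
    kept <- hits[keep, , drop = FALSE]
    groups <- lapply(split(kept$contig_id, kept$marker_id), unique)
    new("MarkerSet", groups = groups)
}

#' Restrict a MarkerSet to a set of contigs
#'
#' Used when estimating the genome number inside one cluster: each
#' marker's contig set is intersected with the cluster members and empty
#' groups are dropped.
#'
#' @param markers a \code{MarkerSet}.
#' @param ids contig ids to keep.
#' @return a \code{MarkerSet}.
#' @export
restrictMarkers <- function(markers, ids) {
    g <- lapply(markerGroups(markers), intersect, y = ids)
    new("MarkerSet", groups = g[lengths(g) > 0L])
}

#' Estimate the number of genomes from marker incidence
#'
#' Each single-copy marker m_i maps to G_i contigs; ideally G_i equals the
#' number of genomes, but markers can be lost (assembly gaps, mapping
#' failures) or multiplied (misassembly). The estimate is taken from the
#' multiset \{G_1, ..., G_M\}: with G_mode its most frequent value (ties
#' broken toward the larger value), G is the largest G_i whose multiplicity
#' is at least half the multiplicity of G_mode. By construction
#' G >= G_mode.
#'
#' @param markers a non-empty \code{MarkerSet}.
#' @return list with elements \code{G} and \code{GMode} (integers).
#' @examples
#' ms <- new("MarkerSet", groups = list(
#'     m1 = c("a", "b", "c"), m2 = c("a", "b", "d"),
#'     m3 = c("b", "c", "d"), m4 = c("a", "b", "c", "d", "e")))
#' estimateGenomeNumber(ms)  # G = 3, GMode = 3
#' @export
estimateGenomeNumber <- function(markers) {
    counts <- markerCounts(markers)
    if (length(counts) == 0L)
        stop("empty marker table: no genome-number estimate available")
    tab <- table(counts)
    vals <- as.integer(names(tab))
    mult <- as.integer(tab)
    gMode <- max(vals[mult == max(mult)])
    modeMult <- mult[vals == gMode]
    G <- max(vals[mult >= 0.5 * modeMult])
    list(G = as.integer(G), GMode = as.integer(gMode))
}
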