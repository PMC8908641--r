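#' Evaluate predicted bins against a ground truth
#'
#' Base-pair-weighted bin quality in the style of assembly-free binning
#' benchmarks: for each predicted bin the dominant genome is the one
#' contributing the most base pairs; precision (purity) is the dominant
#' genome's share of the bin's bp; recall (completeness) is the share of
#' that genome's total bp captured by the bin; F1 is their harmonic mean.
#' Each genome is credited to at most one bin by a greedy best-F1
#' one-to-one matching. Bins with precision >= 0.95 and recall >= 0.90
#' among the matched ones count as high-quality.
#'
#' @param predicted a \code{\link{BinningResult}} or a membership
#'   data.frame with columns \code{contig_id}, \code{cluster_id},
#'   \code{status}; only \code{status == "output"} rows are scored.
#' @param truth data.frame with columns \code{contig_id},
#'   \code{genome_id}, \code{length} (bp), covering every predicted
#'   contig.
#' @return list with \code{perCluster} (data.frame: cluster_id,
#'   genome_id, cluster_bp, precision, recall, f1, matched),
#'   \code{genomeRecall} (named vector: recall of each genome from its
#'   matched bin, 0 when unmatched) and \code{summary} (nClusters,
#'   highQuality).
#' @export
evaluateClusters <- function(predicted, truth) {
    if (is(predicted, "BinningResult"))
        predicted <- membership(predicted)
    stopifnot(all(c("contig_id", "cluster_id", "status") %in%
        names(predicted)))
    unknown <- setdiff(predicted$contig_id, truth$contig_id)
    if (length(unknown))
        stop("predicted contig(s) absent from truth: ",
            paste(utils::head(unknown, 10L), collapse = ", "))
    genomeBp <- tapply(truth$length, truth$genome_id, sum)
    out <- predicted[predicted$status == "output", , drop = FALSE]
    genomes <- sort(unique(truth$genome_id))
    genomeRecall <- stats::setNames(numeric(length(genomes)), genomes)
    if (nrow(out) == 0L)
        return(list(
            perCluster = data.frame(cluster_id = character(),
                genome_id = character(), cluster_bp = numeric(),
                precision = numeric(), recall = numeric(),
                f1 = numeric(), matched = logical()),
            genomeRecall = genomeRecall,
            summary = list(nClusters = 0L, highQuality = 0L)))
    ti <- match(out$contig_id, truth$contig_id)
    out$genome <- truth$genome_id[ti]
    out$bp <- truth$length[ti]
    rows <- lapply(split(out, out$cluster_id), function(cl) {
        byGenome <- tapply(cl$bp, cl$genome, sum)
        dom <- names(byGenome)[which.max(byGenome)]
        prec <- max(byGenome) / sum(cl$bp)
        rec <- max(byGenome) / genomeBp[[dom]]
        data.frame(cluster_id = cl$cluster_id[1L], genome_id = dom,
            cluster_bp = sum(cl$bp), precision = prec, recall = rec,
            f1 = 2 * prec * rec / (prec + rec),
            stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, rows)
    rownames(per) <- NULL
    per <- per[order(-per$f1, per$cluster_id), , drop = FALSE]
    taken <- character()
    per$matched <- FALSE
    for (i in seq_len(nrow(per))) {
        if (!(per$genome_id[i] %in% taken)) {
            per$matched[i] <- TRUE
            taken <- c(taken, per$genome_id[i])
            genomeRecall[per$genome_id[i]] <- per$recall[i]
        }
    }
    list(perCluster = per, genomeRecall = genomeRecall,
        summary = list(
            nClusters = nrow(per),
            highQuality = sum(per$matched & per$precision >= 0.95 &
                per$recall >= 0.90)))
}
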