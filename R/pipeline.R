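#' Refine one preliminary cluster with the second layer
#'
#' Estimates the genome number G inside the cluster from its marker hits.
#' A cluster with G = 1 (or with no markers at all) is emitted intact when
#' it exceeds \code{minClusterSize} bp; otherwise the cluster is split:
#' marker-sharing groups are selected, cross-predicted into an adjacency
#' matrix, spectrally clustered into G extended seeds, the composition
#' classifier is trained on seed sub-fragments, and the KL-regularized
#' coverage mixture partitions all cluster contigs. Each resulting
#' sub-cluster larger than \code{minClusterSize} bp whose own marker-based
#' genome-number estimate is 1 (no markers: judged by size alone) is
#' emitted; everything else becomes leftover for the next round.
#'
#' @param contigs named \code{DNAStringSet}: the cluster members.
#' @param markers \code{MarkerSet} already restricted to these contigs.
#' @param coverage depth matrix (rownames covering the members).
#' @param k k-mer size.
#' @param minClusterSize minimum emitted cluster size in bp (default
#'   200 kb).
#' @param seed integer seed.
#' @param verbose emit progress messages.
#' @return list with \code{emitted} (list of lists: \code{ids},
#'   \code{estimatedG}) and \code{leftover} (character vector of contig
#'   ids).
#' @export
runSecondLayer <- function(contigs, markers, coverage, k = 4L,
        minClusterSize = 2e5, seed = 1L, verbose = FALSE) {
    ids <- names(contigs)
    bp <- sum(Biostrings::width(contigs))
    emitWhole <- function(G) list(
        emitted = list(list(ids = ids, estimatedG = G)),
        leftover = character())
    asLeftover <- list(emitted = list(), leftover = ids)
    groups <- markerGroups(markers)
    if (length(groups) == 0L) {
        vlog(verbose, "  cluster without markers (%.0f bp): %s", bp,
            if (bp > minClusterSize) "emitted by size" else "leftover")
        return(if (bp > minClusterSize) emitWhole(NA_integer_)
            else asLeftover)
    }
    est <- estimateGenomeNumber(markers)
    if (est$G == 1L)
        return(if (bp > minClusterSize) emitWhole(1L) else asLeftover)
    sel <- tryCatch(selectGroups(markers, est$GMode),
        error = function(e) NULL)
    if (is.null(sel) ||
            !any(vapply(sel, length, integer(1)) >= 2L))
        return(asLeftover)  # unseedable
    logCov <- log(coverage[ids, , drop = FALSE] + 1)
    A <- buildAdjacency(sel, contigs, logCov, k = k,
        seed = childSeed(seed, 1L))
    G <- min(est$G, nrow(A))
    partition <- spectralSeedClusters(A, G, seed = childSeed(seed, 2L))
    seeds <- buildSeeds(partition, contigs)
    model <- trainKmerModel(seeds, k = k, seed = childSeed(seed, 3L))
    pSvm <- predictPSvm(model, contigs)
    fit <- runCoverageGmm(logCov, pSvm, W = 1 / ncol(logCov))
    emitted <- list()
    leftover <- character()
    for (g in unique(fit$assignment)) {
        sub <- ids[fit$assignment == g]
        subBp <- sum(Biostrings::width(contigs[sub]))
        subMarkers <- restrictMarkers(markers, sub)
        subG <- if (length(markerGroups(subMarkers)) == 0L) NA_integer_
            else estimateGenomeNumber(subMarkers)$G
        if (subBp > minClusterSize && (is.na(subG) || subG == 1L))
            emitted <- c(emitted, list(list(ids = sub,
                estimatedG = subG)))
        else
            leftover <- c(leftover, sub)
    }
    vlog(verbose, "  split G=%d cluster (%.0f bp): %d emitted, %d leftover",
        est$G, bp, length(emitted), length(leftover))
    list(emitted = emitted, leftover = leftover)
}

#' Bin metagenomic contigs with the two-layer model
#'
#' End-to-end driver. Contigs shorter than \code{minSequenceLength} are
#' dropped; canonical k-mer frequencies, PCA reduction and log coverages
#' are assembled into first-layer features; the genome number G is
#' estimated from the markers (fallback without markers:
#' max(10, total bp / 4 Mb)); the first layer starts at 3 G components,
#' dissolves under-sized ones and screens compositionally heterogeneous
#' clusters (flagged abnormal and excluded); each surviving preliminary
#' cluster passes through \code{\link{runSecondLayer}}. Leftover contigs
#' are pooled assembly-wide and the whole two-layer procedure repeats
#' until no contigs remain, a full round emits nothing, or
#' \code{maxRounds} is reached; the remainder is reported unclustered.
#'
#' @param contigs a named \code{DNAStringSet} or FASTA path.
#' @param coverage a depth matrix with contig rownames or a coverage TSV
#'   path (see \code{\link{readCoverageTable}}).
#' @param markerHits a marker-hit data.frame, a TSV path (see
#'   \code{\link{readMarkerHits}}), or \code{NULL} for the no-marker
#'   fallback.
#' @param minSequenceLength minimum contig length in bp (default 2500).
#' @param maxDpgmmDistance abnormality cutoff on the average pairwise
#'   k-mer profile distance (default 0.04).
#' @param minClusterSize minimum emitted cluster size in bp (default
#'   200 kb).
#' @param k k-mer size (default 4).
#' @param maxRounds maximum number of recycling rounds (default 10).
#' @param seed master seed; all stochastic steps derive child seeds from
#'   it.
#' @param verbose emit per-round progress messages.
#' @return a \code{\link{BinningResult}}.
#' @export
binContigs <- function(contigs, coverage, markerHits = NULL,
        minSequenceLength = 2500L, maxDpgmmDistance = 0.04,
        minClusterSize = 2e5, k = 4L, maxRounds = 10L, seed = 1L,
        verbose = FALSE) {
    if (is.character(contigs) && length(contigs) == 1L)
        contigs <- readContigs(contigs)
    if (is.character(coverage) && length(coverage) == 1L)
        coverage <- readCoverageTable(coverage)
    if (is.character(markerHits) && length(markerHits) == 1L)
        markerHits <- readMarkerHits(markerHits)
    contigs <- filterByLength(contigs, minSequenceLength)
    if (length(contigs) == 0L)
        stop("no contig passes the length filter")
    ids <- names(contigs)
    missing <- setdiff(ids, rownames(coverage))
    if (length(missing))
        stop("contigs missing from the coverage table: ",
            paste(utils::head(missing, 10L), collapse = ", "))
    markers <- if (is.null(markerHits))
        new("MarkerSet", groups = list())
    else
        restrictMarkers(filterMarkerHits(markerHits), ids)
    idx <- canonicalKmerIndex(k)
    kmerAll <- kmerFrequencies(contigs, k = k, index = idx)
    lengthsAll <- stats::setNames(as.numeric(Biostrings::width(contigs)),
        ids)
    status <- stats::setNames(rep(NA_character_, length(ids)), ids)
    clusterId <- stats::setNames(rep(NA_character_, length(ids)), ids)
    estG <- integer()
    binCounter <- 0L
    pool <- ids
    for (round in seq_len(maxRounds)) {
        if (length(pool) < 2L)
            break
        poolMarkers <- restrictMarkers(markers, pool)
        G <- tryCatch(estimateGenomeNumber(poolMarkers)$G,
            error = function(e) NA_integer_)
        if (is.na(G))
            G <- max(10L, ceiling(sum(lengthsAll[pool]) / 4e6))
        GInit <- 3L * G
        kmer <- kmerAll[pool, , drop = FALSE]
        red <- pcaReduce(kmer)
        x <- cbind(red, log(coverage[pool, , drop = FALSE] + 1))
        w <- lengthsAll[pool] / mean(lengthsAll[pool])
        layer1 <- runFirstLayer(x, w, lengthsAll[pool], GInit,
            kmerProfiles = kmer, maxDistance = maxDpgmmDistance,
            seed = childSeed(seed, round))
        vlog(verbose, "round %d: %d contigs, G=%d, %d preliminary clusters",
            round, length(pool), G, length(layer1$clusters))
        emittedThisRound <- 0L
        removedThisRound <- 0L
        leftover <- character()
        for (ci in seq_along(layer1$clusters)) {
            cl <- layer1$clusters[[ci]]
            clIds <- pool[cl$members]
            if (cl$abnormal) {
                status[clIds] <- "abnormal"
                clusterId[clIds] <- "abnormal"
                removedThisRound <- removedThisRound + length(clIds)
                vlog(verbose,
                    "  abnormal cluster (%d contigs, avg distance %.3f)",
                    length(clIds), cl$avgDistance)
                next
            }
            res <- runSecondLayer(contigs[clIds],
                restrictMarkers(markers, clIds), coverage, k = k,
                minClusterSize = minClusterSize,
                seed = childSeed(seed, 1000L * round + ci),
                verbose = verbose)
            for (em in res$emitted) {
                binCounter <- binCounter + 1L
                bid <- sprintf("bin_%03d", binCounter)
                status[em$ids] <- "output"
                clusterId[em$ids] <- bid
                estG <- c(estG, stats::setNames(
                    ifelse(is.na(em$estimatedG), 1L, em$estimatedG), bid))
                emittedThisRound <- emittedThisRound + 1L
            }
            leftover <- c(leftover, res$leftover)
        }
        pool <- leftover
        if (emittedThisRound == 0L && removedThisRound == 0L)
            break
    }
    status[is.na(status)] <- "unclustered"
    clusterId[is.na(clusterId)] <- "unclustered"
    mem <- data.frame(contig_id = ids, cluster_id = unname(clusterId[ids]),
        status = unname(status[ids]), stringsAsFactors = FALSE)
    summ <- do.call(rbind, lapply(split(mem, mem$cluster_id), function(m) {
        st <- m$status[1L]
        data.frame(cluster_id = m$cluster_id[1L], n_contigs = nrow(m),
            total_bp = sum(lengthsAll[m$contig_id]),
            estimated_G = if (m$cluster_id[1L] %in% names(estG))
                as.integer(estG[[m$cluster_id[1L]]]) else NA_integer_,
            status = st, stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL
    summ <- summ[order(summ$status, summ$cluster_id), , drop = FALSE]
    new("BinningResult", membership = mem, clusters = summ)
}

#' Write bins to disk
#'
#' Writes one FASTA per emitted bin, a \code{membership.tsv} with columns
#' contig_id, cluster_id, status, and optionally the unclustered (and
#' abnormal) contigs as \code{unclustered.fasta}.
#'
#' @param result a \code{BinningResult}.
#' @param contigs the named \code{DNAStringSet} that was binned.
#' @param dir output directory (created if needed).
#' @param outputUnclustered also write non-output contigs to FASTA.
#' @return \code{dir}, invisibly.
#' @export
writeBins <- function(result, contigs, dir, outputUnclustered = FALSE) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    mem <- membership(result)
    utils::write.table(mem, file.path(dir, "membership.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    for (bid in unique(mem$cluster_id[mem$status == "output"])) {
        sel <- mem$contig_id[mem$cluster_id == bid]
        writeContigs(contigs[sel], file.path(dir, paste0(bid, ".fasta")))
    }
    if (outputUnclustered) {
        sel <- mem$contig_id[mem$status != "output"]
        if (length(sel))
            writeContigs(contigs[sel],
                file.path(dir, "unclustered.fasta"))
    }
    invisible(dir)
}
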