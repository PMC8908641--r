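#' PCA-reduce k-mer frequency profiles
#'
#' Principal component analysis of the mean-centered (not scaled: all
#' columns share a unit) profile matrix, retaining the smallest number of
#' leading components whose cumulative explained variance reaches
#' \code{varianceRetained}. Keeping at least 90\% of the compositional
#' variance preserves genome-level separation while letting the coverage
#' coordinates matter when composition alone is uninformative.
#'
#' @param profiles numeric matrix, contigs x k-mer columns.
#' @param varianceRetained fraction of variance to keep (default 0.90).
#' @return score matrix (contigs x p, p >= 1), rownames preserved.
#' @export
pcaReduce <- function(profiles, varianceRetained = 0.90) {
    stopifnot(nrow(profiles) >= 2L, varianceRetained > 0,
        varianceRetained <= 1)
    pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
    v <- pc$sdev^2
    tot <- sum(v)
    if (tot <= 0) {
        warning("zero total variance; returning a single all-zero score")
        out <- matrix(0, nrow(profiles), 1L,
            dimnames = list(rownames(profiles), "PC1"))
        return(out)
    }
    cum <- cumsum(v) / tot
    p <- which(cum >= varianceRetained - 1e-12)[1L]
    if (is.na(p)) p <- length(v)
    pc$x[, seq_len(max(p, 1L)), drop = FALSE]
}

#' Per-contig coverage from a SAM/BAM alignment
#'
#' Coverage of a contig in one sample is the mean number of aligned bases
#' per position: the sum over retained reads of reference-consuming aligned
#' bases (CIGAR M/=/X) divided by the contig length. Retained reads are
#' mapped, primary, non-supplementary alignments with MAPQ >=
#' \code{minMapq} (the uniquely-aligned-read convention; default 20).
#'
#' @param path a SAM or BAM file (SAM is converted on the fly).
#' @param contigs named \code{DNAStringSet} of the assembly (the universe
#'   of contig ids).
#' @param minMapq minimum mapping quality.
#' @return named numeric vector of depths, one entry per contig in
#'   \code{contigs} (0 for contigs with no retained read).
#' @export
coverageFromAlignments <- function(path, contigs, minMapq = 20L) {
    stopifnot(file.exists(path))
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        path <- Rsamtools::asBam(path, destination = dest,
            overwrite = TRUE, indexDestination = FALSE)
    }
    param <- Rsamtools::ScanBamParam(
        flag = Rsamtools::scanBamFlag(
            isUnmappedQuery = FALSE,
            isSecondaryAlignment = FALSE,
            isSupplementaryAlignment = FALSE),
        mapqFilter = minMapq)
    aln <- GenomicAlignments::readGAlignments(path, param = param)
    ids <- names(contigs)
    depth <- stats::setNames(numeric(length(ids)), ids)
    if (length(aln)) {
        seqn <- as.character(GenomicAlignments::seqnames(aln))
        unknown <- setdiff(unique(seqn), ids)
        if (length(unknown))
            stop("alignment references contig(s) absent from the assembly: ",
                paste(unknown, collapse = ", "))
        ops <- GenomicAlignments::cigarOpTable(
            GenomicAlignments::cigar(aln))
        alignedBases <- rowSums(ops[, c("M", "=", "X"), drop = FALSE])
        per <- rowsum(alignedBases, group = seqn)
        depth[rownames(per)] <- per[, 1L] /
            Biostrings::width(contigs)[match(rownames(per), ids)]
    }
    depth
}

#' Read / write a coverage table
#'
#' Tab-delimited with a header row; first column is the contig id, the
#' remaining columns are per-sample mean depths. This bypasses SAM/BAM
#' entirely when depths were computed elsewhere.
#'
#' @param path TSV file path.
#' @return numeric matrix with contig ids as rownames, one column per
#'   sample.
#' @export
readCoverageTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
        check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("coverage table needs a contig id column plus >= 1 sample")
    if (anyDuplicated(df[[1L]]))
        stop("duplicate contig ids in coverage table")
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    if (any(!is.finite(m)) || any(m < 0))
        stop("coverage values must be finite and non-negative")
    rownames(m) <- as.character(df[[1L]])
    m
}

#' @rdname readCoverageTable
#' @param coverage numeric matrix with contig rownames.
#' @export
writeCoverageTable <- function(coverage, path) {
    df <- data.frame(contig_id = rownames(coverage), coverage,
        check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Assemble per-contig features for the first clustering layer
#'
#' Computes canonical k-mer frequencies, their PCA reduction, and bundles
#' them with the per-sample depths, lengths and length-derived weights
#' w_c = l_c / mean(l) into a \code{\link{ContigFeatures}} object. The
#' first-layer input vector of contig c is
#' \code{[reduced composition, log(depth + 1)]}; longer contigs get
#' proportionally larger weight because they estimate both signals more
#' reliably.
#'
#' @param contigs named \code{DNAStringSet}.
#' @param coverage numeric matrix of depths with contig rownames covering
#'   all contigs (extra rows ignored).
#' @param k k-mer size (default 4).
#' @param varianceRetained PCA variance fraction retained (default 0.90).
#' @param kmer optional precomputed k-mer frequency matrix for these
#'   contigs (rows in contig order), to avoid recounting.
#' @return a \code{ContigFeatures} object.
#' @export
contigFeatures <- function(contigs, coverage, k = 4L,
        varianceRetained = 0.90, kmer = NULL) {
    ids <- names(contigs)
    if (is.null(ids) || anyDuplicated(ids))
        stop("contigs must be uniquely named")
    missing <- setdiff(ids, rownames(coverage))
    if (length(missing))
        stop("contigs missing from coverage table: ",
            paste(utils::head(missing, 10L), collapse = ", "))
    if (is.null(kmer))
        kmer <- kmerFrequencies(contigs, k = k)
    red <- pcaReduce(kmer, varianceRetained)
    lens <- as.numeric(Biostrings::width(contigs))
    new("ContigFeatures",
        contigIds = ids,
        lengths = lens,
        weights = lens / mean(lens),
        kmerFreq = kmer,
        reduced = red,
        coverage = coverage[ids, , drop = FALSE],
        k = as.integer(k))
}
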