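#' Specification of a synthetic metagenomic community
#'
#' Parameter bag for \code{\link{generateCommunity}}. The defaults emulate
#' a small multi-sample shotgun study: 5 genomes of ~2 Mb each (~10 Mb of
#' assembly), 2 sequencing samples with per-genome mean depths drawn
#' log-normally around 20x (roughly the 10--40x range), contigs of
#' 10--30 kb, and 40 single-copy markers placed one per genome with 5\%
#' dropout and 5\% duplication.
#'
#' @param G number of genomes.
#' @param genomeBp target assembly bp per genome.
#' @param markovOrder order of the per-genome Markov composition model.
#' @param nSamples number of sequencing samples.
#' @param depthLaw named vector \code{c(meanlog=, sdlog=)} of the
#'   log-normal law for per-genome per-sample mean depth.
#' @param depthNoiseSd sdlog of the per-contig multiplicative log-normal
#'   depth noise (overdispersion beyond a shared genome mean).
#' @param contigLenRange integer bounds of the uniform contig length law.
#' @param markerCount number of single-copy markers.
#' @param dropout probability that a (marker, genome) incidence is lost.
#' @param duplication probability that an incidence gains an extra contig.
#' @param seed integer seed; the whole community is a deterministic
#'   function of the spec.
#' @return a validated list of class \code{CommunitySpec}.
#' @export
communitySpec <- function(G = 5L, genomeBp = 2e6, markovOrder = 2L,
        nSamples = 2L, depthLaw = c(meanlog = log(20), sdlog = 0.45),
        depthNoiseSd = 0.1, contigLenRange = c(10000L, 30000L),
        markerCount = 40L, dropout = 0.05, duplication = 0.05,
        seed = 1L) {
    spec <- list(G = as.integer(G), genomeBp = genomeBp,
        markovOrder = as.integer(markovOrder),
        nSamples = as.integer(nSamples), depthLaw = depthLaw,
        depthNoiseSd = depthNoiseSd,
        contigLenRange = as.integer(contigLenRange),
        markerCount = as.integer(markerCount), dropout = dropout,
        duplication = duplication, seed = as.integer(seed))
    stopifnot(spec$G >= 1L, spec$nSamples >= 1L, spec$markovOrder >= 1L,
        spec$markerCount >= 1L, spec$dropout >= 0, spec$dropout <= 1,
        spec$duplication >= 0, spec$duplication <= 1,
        length(spec$contigLenRange) == 2L,
        spec$contigLenRange[1L] >= 100L,
        spec$contigLenRange[2L] >= spec$contigLenRange[1L])
    if (spec$genomeBp < spec$contigLenRange[2L])
        stop("genomeBp must be at least the maximum contig length")
    class(spec) <- "CommunitySpec"
    spec
}

# vectorized order-o Markov generation of `lens` sequences sharing one
# transition matrix (rows: 4^o states, cols: A/C/G/T)
markovSequences <- function(trans, lens, order) {
    m <- length(lens)
    N <- max(lens)
    nStates <- 4L^order
    cum <- t(apply(trans, 1L, cumsum))
    chars <- matrix(0L, m, N)
    for (t in seq_len(order))
        chars[, t] <- sample.int(4L, m, replace = TRUE)
    pow <- 4L^(seq_len(order) - 1L)
    state <- as.integer((chars[, seq_len(order), drop = FALSE] - 1L) %*%
        rev(pow)) + 1L
    base <- 4L^(order - 1L)
    for (t in (order + 1L):N) {
        u <- stats::runif(m)
        cc <- cum[state, , drop = FALSE]
        nxt <- 1L + (u > cc[, 1L]) + (u > cc[, 2L]) + (u > cc[, 3L])
        chars[, t] <- nxt
        state <- ((state - 1L) %% base) * 4L + nxt
    }
    alphabet <- c("A", "C", "G", "T")
    vapply(seq_len(m), function(i)
        paste(alphabet[chars[i, seq_len(lens[i])]], collapse = ""),
        character(1))
}

#' Generate a synthetic community
#'
#' Each genome gets its own randomly drawn order-k Markov chain (rows of
#' the transition matrix are independent Dirichlet(1) draws), so genomes
#' carry distinct, internally homogeneous tetramer compositions. Genomes
#' are emitted directly as contigs with lengths uniform on
#' \code{contigLenRange} (enough contigs to reach \code{genomeBp}).
#' Per-sample genome depths follow \code{depthLaw}; each contig's depth
#' multiplies its genome's depth by log-normal noise with sdlog
#' \code{depthNoiseSd}. Each marker is placed on one random contig per
#' genome, thinned by \code{dropout} and duplicated (a second contig of
#' the same genome) at rate \code{duplication}; hit coverage/accuracy
#' fields are drawn above the validity thresholds.
#'
#' @param spec a \code{\link{communitySpec}}.
#' @param dir optional directory; when given, writes
#'   \code{contigs.fasta}, \code{coverage.tsv}, \code{markers.tsv} and
#'   \code{truth.tsv} there.
#' @return list with \code{contigs} (\code{DNAStringSet}),
#'   \code{coverage} (matrix), \code{markerHits} (data.frame),
#'   \code{truth} (data.frame contig_id, genome_id, length) and
#'   \code{spec}.
#' @export
generateCommunity <- function(spec = communitySpec(), dir = NULL) {
    stopifnot(inherits(spec, "CommunitySpec"))
    set.seed(spec$seed)
    nStates <- 4L^spec$markovOrder
    ids <- character()
    genomeOf <- character()
    seqs <- character()
    for (g in seq_len(spec$G)) {
        lens <- integer()
        span <- spec$contigLenRange[2L] - spec$contigLenRange[1L] + 1L
        while (sum(lens) < spec$genomeBp)
            lens <- c(lens, spec$contigLenRange[1L] +
                sample.int(span, 1L) - 1L)
        trans <- matrix(stats::rgamma(nStates * 4L, shape = 1),
            nStates, 4L)
        trans <- trans / rowSums(trans)
        gSeqs <- markovSequences(trans, lens, spec$markovOrder)
        gIds <- sprintf("g%02d_c%03d", g, seq_along(lens))
        ids <- c(ids, gIds)
        genomeOf <- c(genomeOf, rep(sprintf("genome_%02d", g),
            length(lens)))
        seqs <- c(seqs, gSeqs)
    }
    contigs <- Biostrings::DNAStringSet(seqs)
    names(contigs) <- ids
    lens <- Biostrings::width(contigs)
    genomeDepth <- matrix(stats::rlnorm(spec$G * spec$nSamples,
        spec$depthLaw[["meanlog"]], spec$depthLaw[["sdlog"]]),
        spec$G, spec$nSamples)
    gIndex <- as.integer(factor(genomeOf,
        levels = sprintf("genome_%02d", seq_len(spec$G))))
    noise <- matrix(stats::rlnorm(length(ids) * spec$nSamples, 0,
        spec$depthNoiseSd), length(ids), spec$nSamples)
    coverage <- genomeDepth[gIndex, , drop = FALSE] * noise
    dimnames(coverage) <- list(ids,
        sprintf("sample_%02d", seq_len(spec$nSamples)))
    hits <- list()
    for (m in seq_len(spec$markerCount)) {
        mid <- sprintf("marker_%03d", m)
        for (g in seq_len(spec$G)) {
            keep <- stats::runif(1) >= spec$dropout
            dup <- stats::runif(1) < spec$duplication
            if (!keep)
                next
            gc <- ids[gIndex == g]
            pick <- sample(gc, min(1L + dup, length(gc)))
            hits[[length(hits) + 1L]] <- data.frame(
                marker_id = mid, contig_id = pick,
                coverage = stats::runif(length(pick), 0.5, 1),
                accuracy = stats::runif(length(pick), 0.6, 1),
                stringsAsFactors = FALSE)
        }
    }
    markerHits <- if (length(hits)) do.call(rbind, hits) else
        data.frame(marker_id = character(), contig_id = character(),
            coverage = numeric(), accuracy = numeric())
    truth <- data.frame(contig_id = ids, genome_id = genomeOf,
        length = as.numeric(lens), stringsAsFactors = FALSE)
    out <- list(contigs = contigs, coverage = coverage,
        markerHits = markerHits, truth = truth, spec = spec)
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        writeContigs(contigs, file.path(dir, "contigs.fasta"))
        writeCoverageTable(coverage, file.path(dir, "coverage.tsv"))
        utils::write.table(markerHits, file.path(dir, "markers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(truth, file.path(dir, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
}
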