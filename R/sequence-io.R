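#' Read an assembly FASTA of contigs
#'
#' Reads a (possibly wrapped) multi-record FASTA and normalizes each
#' sequence: uppercased, U mapped to T, and any residual character outside
#' \code{A/C/G/T} mapped to \code{N}. Record ids are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return a \code{\link[Biostrings]{DNAStringSet}} named by contig id.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1", "ACGTACGT", ">c2", "acg-t"), tf)
#' readContigs(tf)
#' @export
readContigs <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    raw <- tryCatch(Biostrings::readBStringSet(path),
        error = function(e) stop("not a readable FASTA file: ", path,
            " (", conditionMessage(e), ")"))
    if (length(raw) == 0L)
        stop("empty FASTA file: ", path)
    ids <- sub("\\s.*$", "", names(raw))
    if (any(ids == ""))
        stop("FASTA record with empty id in ", path)
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate contig id(s) in ", path, ": ",
            paste(dup, collapse = ", "))
    seqs <- chartr("U", "T", toupper(as.character(raw)))
    seqs <- gsub("[^ACGT]", "N", seqs)
    empty <- !nzchar(seqs)
    if (any(empty))
        stop("empty sequence for record(s): ",
            paste(ids[empty], collapse = ", "))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    out
}

#' Write contigs to FASTA
#'
#' @param contigs a named \code{DNAStringSet}.
#' @param path output file path.
#' @param width line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
writeContigs <- function(contigs, path, width = 80L) {
    Biostrings::writeXStringSet(contigs, path, width = width)
    invisible(path)
}

#' Drop contigs below a minimum length
#'
#' Short contigs carry noisy k-mer and coverage signals; the default cutoff
#' of 2,500 bp is the binner's standard minimum sequence length
#' (option \code{--min_sequence_length} on the command line).
#'
#' @param contigs a \code{DNAStringSet}.
#' @param minLength minimum length in bp (inclusive).
#' @return the subset of \code{contigs} with width >= \code{minLength},
#'   input order preserved.
#' @export
filterByLength <- function(contigs, minLength = 2500L) {
    stopifnot(minLength >= 1L)
    contigs[Biostrings::width(contigs) >= minLength]
}

#' Sample random sub-fragments of a sequence
#'
#' Draws \code{count} fragments whose lengths are uniform on the integer
#' interval \code{[minLen, min(maxLen, nchar(seq))]} and whose start
#' positions are uniform over the admissible offsets. Used to build
#' classifier training sets: 20 sub-contigs of 1.5--2.5 kb per contig for
#' the seed-selection classifier, and 300 sub-seeds of 3--4 kb per extended
#' seed for the composition classifier. Sampling consumes the current R RNG
#' stream, so results are reproducible under \code{set.seed}.
#'
#' If the sequence is shorter than \code{minLen} the whole sequence is
#' returned once per requested fragment (degenerate fallback), so that
#' short marker-bearing contigs still contribute training material.
#'
#' @param seq a single character string or \code{DNAString}.
#' @param count number of fragments.
#' @param minLen,maxLen fragment length bounds in bp.
#' @return a \code{DNAStringSet} of \code{count} fragments with
#'   \code{start} and \code{length} metadata columns.
#' @export
sampleFragments <- function(seq, count, minLen, maxLen) {
    s <- as.character(seq)
    n <- nchar(s)
    stopifnot(count >= 1L, minLen >= 1L, maxLen >= minLen)
    if (n < minLen) {
        frags <- rep(s, count)
        starts <- rep(1L, count)
        lens <- rep(n, count)
    } else {
        hi <- min(maxLen, n)
        lens <- minLen + sample.int(hi - minLen + 1L, count,
            replace = TRUE) - 1L
        starts <- vapply(lens, function(L)
            sample.int(n - L + 1L, 1L), integer(1))
        frags <- substring(s, starts, starts + lens - 1L)
    }
    out <- Biostrings::DNAStringSet(frags)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(start = starts,
        length = lens)
    out
}
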