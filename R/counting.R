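#' Count 5'-anchored C-to-T transitions for one reference
#'
#' Walks each alignment in read orientation and tallies, at every distance
#' \code{i = 0..k} from the read's 5' end, how often a reference C is read as
#' T (\code{ctCounts}) versus read as C (\code{ccCounts}). For reverse-strand
#' alignments the distance is measured from the alignment end corresponding to
#' the read's 5' end and bases are complemented, so a reference G read as A on
#' the forward reference strand contributes a C-to-T observation.
#'
#' Distances are counted along the aligned read: insertions advance the
#' distance but contribute no counts; soft-clipped bases are skipped; only
#' match/mismatch columns are informative. Reference bases come from
#' \code{reference} when supplied, otherwise from each record's MD tag.
#'
#' @param reads a list or data.frame of parsed alignment fields with elements
#'   \code{seq} (character, SEQ as stored, i.e. reference orientation),
#'   \code{cigar}, \code{pos} (1-based leftmost position), \code{reverse}
#'   (logical) and optionally \code{md} (MD tag strings, may contain NA when
#'   \code{reference} is given).
#' @param referenceName name of the reference sequence.
#' @param referenceLength reference length in bp.
#' @param reference reference sequence as a single character string or
#'   \link[Biostrings]{DNAString}; \code{NULL} to use MD tags.
#' @param k window extent: positions \code{0..k} from the 5' end are counted
#'   (default 35).
#'
#' @return a \linkS4class{TransitionCounts} object.
#' @examples
#' reads <- data.frame(seq = "TAAA", cigar = "4M", pos = 1L, reverse = FALSE,
#'                     md = "0C3")
#' countTransitions(reads, "ctg", 10, k = 3)
#' @export
countTransitions <- function(reads, referenceName, referenceLength,
                             reference = NULL, k = 35L) {
    stopifnot(k >= 1L)
    refchar <- if (is.null(reference)) "" else as.character(reference)
    n <- length(reads$seq)
    md <- if (!is.null(reads$md)) as.character(reads$md)
          else rep(NA_character_, n)
    if (nzchar(refchar) == FALSE && anyNA(md) && n > 0L)
        stop("no reference FASTA and missing MD tags for reference '",
             referenceName, "'")
    res <- count_transitions_cpp(
        as.character(reads$seq), as.character(reads$cigar),
        as.integer(reads$pos), as.logical(reads$reverse),
        md, refchar, as.integer(k))
    new("TransitionCounts",
        reference = as.character(referenceName),
        ctCounts = res$N, ccCounts = res$M,
        nReads = as.integer(res$n_reads),
        referenceLength = as.numeric(referenceLength),
        alignedBases = as.numeric(res$aligned_bases))
}

#' Per-position C-to-T transition proportions
#'
#' For each distance \code{i} from the 5' end, the proportion
#' \code{p_hat[i] = N[i] / (M[i] + N[i])} of reference-C sites read as T.
#' Positions with no observations (\code{M[i] + N[i] == 0}) are flagged
#' non-informative and carry \code{NA}, never a coerced 0/0.
#'
#' @param x a \linkS4class{TransitionCounts} object.
#' @return a data.frame with columns \code{position} (0-based distance),
#'   \code{pHat} and \code{informative}.
#' @rdname damageProportions
#' @export
setMethod("damageProportions", "TransitionCounts", function(x) {
    N <- x@ctCounts
    M <- x@ccCounts
    tot <- N + M
    inf <- tot > 0L
    p <- ifelse(inf, N / pmax(tot, 1L), NA_real_)
    data.frame(position = seq_along(N) - 1L, pHat = p, informative = inf)
})

#' Mean coverage (depth) of a reference
#'
#' Total matched read bases divided by the reference length: the mean number
#' of aligned read bases per reference position (depth, not breadth).
#'
#' @param x a \linkS4class{TransitionCounts} object.
#' @return a non-negative number.
#' @rdname meanCoverage
#' @export
setMethod("meanCoverage", "TransitionCounts", function(x) {
    if (x@referenceLength <= 0)
        stop("reference length must be positive for reference '",
             x@reference, "'")
    x@alignedBases / x@referenceLength
})

## ---- alignment file access -------------------------------------------------

## Normalise a SAM/BAM/CRAM path to an indexed BAM, converting when needed.
## Returns the BAM path; temporary conversions land in tempdir().
prepareBamInput <- function(path) {
    if (!file.exists(path)) stop("alignment file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext == "sam") {
        dest <- tempfile(fileext = "")
        bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                                indexDestination = TRUE)
        return(bam)
    }
    if (!file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path))) {
        sorted <- tryCatch({
            dest <- tempfile()
            Rsamtools::sortBam(path, dest)
        }, error = function(e)
            stop("failed to read alignment file '", path, "': ",
                 conditionMessage(e)))
        Rsamtools::indexBam(sorted)
        return(sorted)
    }
    path
}

## Fetch the records of one reference from an indexed BAM, applying the
## record-level filters (unmapped / secondary / supplementary / QC-fail
## dropped; duplicates kept; optional MAPQ floor).
scanReference <- function(bam, refName, refLen, minMapq = 0L) {
    flags <- Rsamtools::scanBamFlag(
        isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
        isSupplementaryAlignment = FALSE, isNotPassingQualityControls = FALSE)
    param <- Rsamtools::ScanBamParam(
        flag = flags,
        what = c("pos", "strand", "cigar", "seq", "mapq"),
        tag = "MD",
        which = GenomicRanges::GRanges(refName,
                                       IRanges::IRanges(1L, refLen)),
        mapqFilter = if (minMapq > 0L) minMapq else NA_integer_)
    res <- Rsamtools::scanBam(bam, param = param)[[1L]]
    list(seq = as.character(res$seq),
         cigar = res$cigar,
         pos = res$pos,
         reverse = as.character(res$strand) == "-",
         md = res$tag$MD)
}
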