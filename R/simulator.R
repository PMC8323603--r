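## Synthetic ancient-DNA dataset generator: reference contigs, fragmented
## reads with geometric 5' C->T deamination, and ground-truth SAM alignments
## emitted from the known placements (no aligner in the loop, so unit
## fixtures carry no mapping noise).

#' Specification of one simulated contig dataset
#'
#' Bundles the generator parameters with their defaults: a lognormal read
#' (fragment) length distribution truncated to \code{[30, 150]} bp with
#' median ~44 bp and mode ~37 bp (typical of well-preserved ancient DNA),
#' geometric deamination decay 0.3 per base, and no sequencing error unless
#' requested.
#'
#' @param contigLength contig length in bp.
#' @param gc GC content of the contig in \code{[0, 1]}.
#' @param coverage target mean depth (aligned bases / contig length).
#' @param damage target terminal 5' C-to-T frequency in \code{[0, 1]}.
#' @param decay geometric decay of the per-position deamination
#'   probability: a C at read position \code{i} deaminates with probability
#'   \code{damage * (1 - decay)^i}.
#' @param seqError per-base sequencing error rate applied after
#'   deamination.
#' @param readLenMeanlog,readLenSdlog lognormal read-length parameters.
#' @param readLenMin,readLenMax truncation bounds in bp.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return a list with class \code{"SimulationSpec"}.
#' @export
simulationSpec <- function(contigLength = 10000L, gc = 0.47,
                           coverage = 20, damage = 0.1, decay = 0.3,
                           seqError = 0,
                           readLenMeanlog = log(44),
                           readLenSdlog = sqrt(log(44) - log(37)),
                           readLenMin = 30L, readLenMax = 150L,
                           seed = 1L) {
    stopifnot(contigLength >= 1L, gc >= 0, gc <= 1, coverage >= 0,
              damage >= 0, damage <= 1, decay > 0, decay < 1,
              seqError >= 0, seqError <= 1, readLenMin >= 1L,
              readLenMax >= readLenMin)
    structure(list(contigLength = as.integer(contigLength), gc = gc,
                   coverage = coverage, damage = damage, decay = decay,
                   seqError = seqError, readLenMeanlog = readLenMeanlog,
                   readLenSdlog = readLenSdlog,
                   readLenMin = as.integer(readLenMin),
                   readLenMax = as.integer(readLenMax),
                   seed = as.integer(seed)),
              class = "SimulationSpec")
}

#' Generate a random reference contig
#'
#' Bases are drawn i.i.d. with \code{P(G) = P(C) = gc / 2} and
#' \code{P(A) = P(T) = (1 - gc) / 2}; deterministic for a given seed.
#'
#' @param length contig length in bp.
#' @param gc GC content in \code{[0, 1]}.
#' @param seed integer seed, or \code{NULL} to use the current RNG stream.
#' @return a \link[Biostrings]{DNAString}.
#' @examples generateReference(100, 0.5, seed = 7)
#' @export
generateReference <- function(length, gc, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    bases <- sample(c("A", "T", "G", "C"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
    Biostrings::DNAString(paste(bases, collapse = ""))
}

## Truncated-lognormal sampler via inverse CDF.
sampleReadLengths <- function(n, spec) {
    lo <- stats::plnorm(spec$readLenMin, spec$readLenMeanlog,
                        spec$readLenSdlog)
    hi <- stats::plnorm(spec$readLenMax, spec$readLenMeanlog,
                        spec$readLenSdlog)
    u <- stats::runif(n, lo, hi)
    pmin(pmax(as.integer(round(stats::qlnorm(u, spec$readLenMeanlog,
                                             spec$readLenSdlog))),
              spec$readLenMin), spec$readLenMax)
}

## Mean of the truncated read-length distribution, for fragment counting.
meanReadLength <- function(spec) {
    x <- spec$readLenMin:spec$readLenMax
    d <- stats::dlnorm(x, spec$readLenMeanlog, spec$readLenSdlog)
    sum(x * d) / sum(d)
}

#' Draw fragment placements for a reference
#'
#' Uniform start positions, lengths from the spec's truncated lognormal,
#' strands Bernoulli(0.5); the fragment count is chosen so that the summed
#' fragment length approximates \code{coverage * contigLength}. Fragments
#' lie entirely within the reference. Uses the current RNG stream.
#'
#' @param refLength reference length in bp.
#' @param spec a [simulationSpec()].
#' @return data.frame with columns \code{start} (1-based), \code{width},
#'   \code{reverse}.
#' @export
simulateFragments <- function(refLength, spec) {
    target <- spec$coverage * refLength
    if (target <= 0)
        return(data.frame(start = integer(0), width = integer(0),
                          reverse = logical(0)))
    n <- max(1L, as.integer(round(target / meanReadLength(spec))))
    width <- pmin(sampleReadLengths(n, spec), refLength)
    start <- 1L + as.integer(floor(stats::runif(n) * (refLength - width + 1)))
    data.frame(start = start, width = width,
               reverse = stats::runif(n) < 0.5)
}

#' Inject 5'-anchored deamination into read sequences
#'
#' Each C at read position \code{i} (0-based from the 5' end) flips to T
#' independently with probability \code{damage * (1 - decay)^i}. Sequences
#' are given and returned in read orientation (5' to 3'). An event log of
#' per-position C sites seen and flipped is kept for truth tables.
#' Sequencing error, when requested, is applied afterwards uniformly to all
#' bases (substitution to a random different base). Uses the current RNG
#' stream.
#'
#' @param reads character vector of read sequences in 5'-to-3' read
#'   orientation.
#' @param spec a [simulationSpec()].
#' @return list with \code{reads} (modified sequences) and \code{events}, a
#'   data.frame with columns \code{position}, \code{c_sites},
#'   \code{flipped}.
#' @export
applyDeamination <- function(reads, spec) {
    maxlen <- if (length(reads)) max(nchar(reads)) else 0L
    horizon <- 0L
    while (horizon < maxlen &&
           spec$damage * (1 - spec$decay)^horizon >= 1e-8)
        horizon <- horizon + 1L
    if (length(reads) && maxlen > 0L && horizon < 1L)
        horizon <- 1L    # always log the terminal position for truth tables
    positions <- seq_len(horizon) - 1L
    cSites <- flipped <- integer(length(positions))
    if (spec$damage > 0) {
        for (i in positions) {
            p <- spec$damage * (1 - spec$decay)^i
            isC <- substr(reads, i + 1L, i + 1L) == "C"
            idx <- which(isC)
            cSites[i + 1L] <- length(idx)
            if (length(idx)) {
                hit <- idx[stats::runif(length(idx)) < p]
                flipped[i + 1L] <- length(hit)
                if (length(hit))
                    substr(reads[hit], i + 1L, i + 1L) <- "T"
            }
        }
    } else if (horizon > 0L) {
        for (i in positions)
            cSites[i + 1L] <- sum(substr(reads, i + 1L, i + 1L) == "C")
    }
    if (spec$seqError > 0 && length(reads)) {
        lens <- nchar(reads)
        total <- sum(lens)
        nErr <- stats::rbinom(1L, total, spec$seqError)
        if (nErr > 0L) {
            at <- sort(sample.int(total, nErr))
            readIdx <- findInterval(at - 1L, cumsum(c(0L, lens)),
                                    rightmost.closed = FALSE)
            within <- at - c(0L, cumsum(lens))[readIdx]
            for (e in seq_len(nErr)) {
                r <- readIdx[e]; pos <- within[e]
                old <- substr(reads[r], pos, pos)
                alt <- setdiff(c("A", "C", "G", "T"), old)
                substr(reads[r], pos, pos) <- sample(alt, 1L)
            }
        }
    }
    list(reads = reads,
         events = data.frame(position = positions, c_sites = cSites,
                             flipped = flipped))
}

#' Simulate one contig and its damaged aligned reads (in memory)
#'
#' Runs the generator end to end for a single spec: reference, fragment
#' placement, deamination, and assembly of SAM-ready records (reverse-strand
#' reads stored reverse-complemented with consistent MD/NM tags).
#'
#' @param spec a [simulationSpec()].
#' @param name reference (contig) name.
#' @return list with \code{reference} (DNAStringSet), \code{records} (a
#'   data.frame of SAM fields sorted by position), and \code{truth} (a
#'   one-row data.frame joining the spec to realized terminal damage and
#'   coverage).
#' @export
simulateContig <- function(spec, name = "contig_1") {
    set.seed(spec$seed)
    ref <- generateReference(spec$contigLength, spec$gc, seed = NULL)
    refchar <- as.character(ref)
    frags <- simulateFragments(spec$contigLength, spec)
    n <- nrow(frags)
    if (n == 0L) {
        reference <- Biostrings::DNAStringSet(stats::setNames(list(ref),
                                                              name))
        return(list(reference = reference,
                    records = emptySamRecords(),
                    truth = truthRow(spec, name, NA_real_, 0, 0L)))
    }
    slice <- substring(refchar, frags$start, frags$start + frags$width - 1L)
    readOri <- slice
    if (any(frags$reverse))
        readOri[frags$reverse] <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(slice[frags$reverse])))
    dam <- applyDeamination(readOri, spec)
    readOri <- dam$reads
    seqRefOri <- readOri
    if (any(frags$reverse))
        seqRefOri[frags$reverse] <- as.character(
            Biostrings::reverseComplement(
                Biostrings::DNAStringSet(readOri[frags$reverse])))
    tags <- md_tags_cpp(seqRefOri, slice)
    ord <- order(frags$start)
    records <- data.frame(
        qname = sprintf("%s_read_%d", name, seq_len(n))[ord],
        flag = ifelse(frags$reverse, 16L, 0L)[ord],
        rname = name,
        pos = frags$start[ord],
        mapq = 60L,
        cigar = sprintf("%dM", frags$width)[ord],
        seq = seqRefOri[ord],
        md = tags$md[ord],
        nm = tags$nm[ord],
        stringsAsFactors = FALSE)
    term <- dam$events[1L, ]
    realizedDamage <- if (term$c_sites > 0)
        term$flipped / term$c_sites else NA_real_
    reference <- Biostrings::DNAStringSet(stats::setNames(list(ref), name))
    list(reference = reference, records = records,
         truth = truthRow(spec, name, realizedDamage,
                          sum(frags$width) / spec$contigLength, n,
                          mean(frags$width)),
         events = dam$events)
}

truthRow <- function(spec, name, realizedDamage, realizedCoverage, nReads,
                     meanReadLength = NA_real_) {
    data.frame(reference = name, contig_length = spec$contigLength,
               gc = spec$gc, coverage_target = spec$coverage,
               damage_target = spec$damage, decay = spec$decay,
               seq_error = spec$seqError, seed = spec$seed,
               realized_terminal_damage = realizedDamage,
               realized_coverage = realizedCoverage, n_reads = nReads,
               mean_read_length = meanReadLength,
               stringsAsFactors = FALSE)
}

emptySamRecords <- function() {
    data.frame(qname = character(0), flag = integer(0), rname = character(0),
               pos = integer(0), mapq = integer(0), cigar = character(0),
               seq = character(0), md = character(0), nm = integer(0),
               stringsAsFactors = FALSE)
}

#' Write simulated contigs and alignments to FASTA + SAM
#'
#' Emits a coordinate-sorted SAM with a complete header (one \code{@SQ} line
#' per contig, \code{SO:coordinate}) and the matching multi-FASTA. MD and NM
#' tags reflect the injected substitutions exactly.
#'
#' @param contigs list of results from [simulateContig()].
#' @param prefix output path prefix; writes \code{<prefix>.fasta} and
#'   \code{<prefix>.sam}.
#' @return list with elements \code{fasta} and \code{sam} (the paths).
#' @export
emitAlignments <- function(contigs, prefix) {
    fastaPath <- paste0(prefix, ".fasta")
    samPath <- paste0(prefix, ".sam")
    reference <- do.call(c, lapply(contigs, `[[`, "reference"))
    Biostrings::writeXStringSet(reference, fastaPath)
    con <- file(samPath, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:coordinate", con)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                       Biostrings::width(reference)), con)
    for (ct in contigs) {
        r <- ct$records
        if (nrow(r) == 0L) next
        writeLines(paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar,
                         "*", 0L, 0L, r$seq, "*",
                         paste0("MD:Z:", r$md), paste0("NM:i:", r$nm),
                         sep = "\t"), con)
    }
    list(fasta = fastaPath, sam = samPath)
}

#' Simulate a multi-contig dataset and write it to disk
#'
#' @param specs list of [simulationSpec()] objects (one per contig); contig
#'   names default to \code{contig_<i>}.
#' @param prefix output path prefix for FASTA/SAM.
#' @param names optional contig names.
#' @return list with \code{fasta}, \code{sam} and \code{truth} (data.frame
#'   of per-contig ground truth).
#' @export
simulateDataset <- function(specs, prefix, names = NULL) {
    if (is.null(names))
        names <- sprintf("contig_%d", seq_along(specs))
    contigs <- Map(simulateContig, specs, names)
    paths <- emitAlignments(contigs, prefix)
    truth <- do.call(rbind, lapply(contigs, `[[`, "truth"))
    rownames(truth) <- NULL
    c(paths, list(truth = truth))
}

#' Simulate a parameter grid of datasets
#'
#' Cartesian product of the requested damage levels, coverages, contig
#' lengths (and optionally GC contents) with replicates; per-cell seeds are
#' derived deterministically from \code{baseSeed}. Each cell becomes one
#' contig in a single combined dataset written as FASTA + SAM beside a
#' machine-readable truth table.
#'
#' @param damage,coverage,contigLength,gc numeric vectors of grid levels.
#' @param replicates replicates per cell.
#' @param baseSeed integer; cell seed is
#'   \code{baseSeed + cell index - 1}.
#' @param prefix output path prefix; also writes \code{<prefix>_truth.csv}.
#' @param ... further arguments passed to [simulationSpec()] (e.g.
#'   \code{seqError}, \code{decay}).
#' @return list with \code{fasta}, \code{sam}, \code{truth} and
#'   \code{truthCsv}.
#' @export
simulateGrid <- function(damage, coverage, contigLength, gc = 0.47,
                         replicates = 1L, baseSeed = 1L, prefix, ...) {
    cells <- expand.grid(damage = damage, coverage = coverage,
                         contigLength = contigLength, gc = gc,
                         replicate = seq_len(replicates),
                         KEEP.OUT.ATTRS = FALSE)
    specs <- lapply(seq_len(nrow(cells)), function(i)
        simulationSpec(contigLength = cells$contigLength[i],
                       gc = cells$gc[i], coverage = cells$coverage[i],
                       damage = cells$damage[i],
                       seed = baseSeed + i - 1L, ...))
    out <- simulateDataset(specs, prefix)
    out$truth$replicate <- cells$replicate
    truthCsv <- paste0(prefix, "_truth.csv")
    utils::write.csv(out$truth, truthCsv, row.names = FALSE)
    c(out, list(truthCsv = truthCsv))
}
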