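#' Estimate ancient DNA damage for every reference in an alignment file
#'
#' The full per-contig pipeline: stream alignments per reference, count
#' 5'-anchored C-to-T transitions, fit the null and geometric-decay damage
#' models to the per-position proportions, compare them with a
#' likelihood-ratio test (chi-squared, 2 df), adjust p-values across all
#' successfully tested references with the Benjamini-Hochberg procedure, and
#' predict per-contig call accuracy with the packaged (or a user-supplied)
#' logistic accuracy model.
#'
#' @param alignFile path to a SAM, BAM or CRAM file of reads mapped to the
#'   contigs. SAM input is converted and indexed on the fly; CRAM requires
#'   \code{fasta}.
#' @param fasta optional path to the reference FASTA. When absent, reference
#'   bases are reconstructed from MD tags (a hard error if neither source is
#'   available for a reference with reads).
#' @param k window extent from the 5' read end; distances \code{0..k} are
#'   modelled (default 35).
#' @param minPositions minimum informative positions to attempt a fit
#'   (default 3); references below it get status \code{insufficient_data}.
#' @param minMapq optional MAPQ floor (default 0: no floor, since contig
#'   mapping of short ancient reads legitimately yields low MAPQ).
#' @param accuracyModel an \linkS4class{AccuracyModel} or \code{NULL} to skip
#'   accuracy prediction; defaults to the packaged model.
#' @param huberDelta Huber loss scale passed to [fitDamageModels()].
#' @param threads number of worker processes for per-contig fitting; output
#'   order is deterministic regardless.
#'
#' @return a \link[S4Vectors]{DataFrame} with one row per reference:
#'   \code{reference}, \code{status} (\code{ok}, \code{insufficient_data} or
#'   \code{fit_failed}), \code{n_reads}, \code{coverage}, \code{reflen},
#'   \code{p0}, \code{p_d}, \code{d_pmin}, \code{d_pmax} (damage at the 5'
#'   terminus), \code{rmse}, \code{lambda}, \code{pvalue}, \code{qvalue},
#'   \code{predicted_accuracy}, and a matrix column \code{fitted} with the
#'   fitted damage curve at distances 0..k. References with a non-\code{ok}
#'   status carry NA statistics and are excluded from the BH family.
#' @seealso [writeDamageCsv()], [filterContigs()], [simulateDataset()]
#' @export
analyzeDamage <- function(alignFile, fasta = NULL, k = 35L,
                          minPositions = 3L, minMapq = 0L,
                          accuracyModel = loadAccuracyModel(),
                          huberDelta = 1.0, threads = 1L) {
    bam <- prepareBamInput(alignFile)
    header <- tryCatch(Rsamtools::scanBamHeader(bam)[[1L]]$targets,
                       error = function(e)
                           stop("failed to read header of '", alignFile,
                                "': ", conditionMessage(e)))
    refseqs <- NULL
    if (!is.null(fasta)) {
        refseqs <- Biostrings::readDNAStringSet(fasta)
        names(refseqs) <- sub("\\s.*$", "", names(refseqs))
    }
    refnames <- names(header)
    if (length(refnames) == 0L)
        return(emptyDamageFrame(k))

    worker <- function(i) {
        rn <- refnames[i]
        rl <- unname(header[[i]])
        reads <- scanReference(bam, rn, rl, minMapq = minMapq)
        ref <- NULL
        if (!is.null(refseqs)) {
            if (!rn %in% names(refseqs))
                stop("reference '", rn, "' missing from FASTA")
            ref <- as.character(refseqs[[rn]])
        }
        counts <- countTransitions(reads, rn, rl, reference = ref, k = k)
        analyzeCounts(counts, minPositions = minPositions,
                      huberDelta = huberDelta)
    }
    rows <- if (threads > 1L)
        parallel::mclapply(seq_along(refnames), worker, mc.cores = threads)
    else
        lapply(seq_along(refnames), worker)
    bad <- vapply(rows, inherits, logical(1), "try-error")
    if (any(bad))   # mclapply wraps worker errors; re-raise the first
        stop(attr(rows[[which(bad)[1L]]], "condition"))

    out <- do.call(rbind, lapply(rows, function(r) r$frame))
    fitted <- do.call(rbind, lapply(rows, function(r) r$fitted))
    res <- S4Vectors::DataFrame(out)
    res$fitted <- fitted

    ok <- res$status == "ok"
    res$qvalue <- NA_real_
    if (any(ok))
        res$qvalue[ok] <- adjustPvalues(res$pvalue[ok])
    res$predicted_accuracy <- NA_real_
    if (!is.null(accuracyModel) && any(ok)) {
        feat <- data.frame(damage = res$d_pmax[ok],
                           coverage = res$coverage[ok],
                           contig_length = res$reflen[ok])
        res$predicted_accuracy[ok] <- predictAccuracy(accuracyModel, feat)
    }
    res
}

## Fit + test a single TransitionCounts; returns a one-row data.frame plus
## the fitted curve (NA-filled when no fit was possible).
analyzeCounts <- function(counts, minPositions = 3L, huberDelta = 1.0) {
    k <- length(counts@ctCounts) - 1L
    cov <- if (counts@referenceLength > 0) meanCoverage(counts) else NA_real_
    base <- data.frame(
        reference = counts@reference, status = "ok",
        n_reads = counts@nReads, coverage = cov,
        reflen = counts@referenceLength,
        p0 = NA_real_, p_d = NA_real_, d_pmin = NA_real_, d_pmax = NA_real_,
        rmse = NA_real_, lambda = NA_real_, pvalue = NA_real_,
        stringsAsFactors = FALSE)
    fitted <- matrix(NA_real_, 1L, k + 1L,
                     dimnames = list(NULL, paste0("CtoT-", 0:k)))
    res <- fitDamageModels(counts, minPositions = minPositions,
                           huberDelta = huberDelta)
    if (res$status != "ok") {
        base$status <- res$status
        return(list(frame = base, fitted = fitted))
    }
    fit <- res$fit
    lrt <- damageLRT(fit)
    base$p0 <- fit@p0
    base$p_d <- fit@pD
    base$d_pmin <- fit@dPmin
    base$d_pmax <- fit@dPmax
    base$rmse <- fit@rmse
    base$lambda <- lrt$lambda
    base$pvalue <- lrt$pvalue
    fitted[1L, ] <- fit@fittedCurve
    list(frame = base, fitted = fitted)
}

emptyDamageFrame <- function(k) {
    res <- S4Vectors::DataFrame(
        reference = character(0), status = character(0),
        n_reads = integer(0), coverage = numeric(0), reflen = numeric(0),
        p0 = numeric(0), p_d = numeric(0), d_pmin = numeric(0),
        d_pmax = numeric(0), rmse = numeric(0), lambda = numeric(0),
        pvalue = numeric(0))
    res$fitted <- matrix(numeric(0), 0L, k + 1L,
                         dimnames = list(NULL, paste0("CtoT-", 0:k)))
    res$qvalue <- numeric(0)
    res$predicted_accuracy <- numeric(0)
    res
}

#' Write per-contig damage results to CSV
#'
#' One row per reference with the frozen column schema
#' \code{reference, status, n_reads, coverage, reflen, p0, p_d, d_pmin,
#' d_pmax, rmse, lambda, pvalue, qvalue, predicted_accuracy, CtoT-0..CtoT-k}.
#' A leading \code{#}-comment line records the package version and the window
#' parameter; missing values are written as empty fields.
#'
#' @param results a DataFrame from [analyzeDamage()].
#' @param path output CSV path.
#' @param comment logical; write the versioned header comment line.
#' @return \code{path}, invisibly.
#' @export
writeDamageCsv <- function(results, path, comment = TRUE) {
    df <- as.data.frame(results[, setdiff(colnames(results), "fitted")])
    fitted <- results$fitted
    if (!is.null(fitted) && nrow(df) == nrow(fitted))
        df <- cbind(df, as.data.frame(fitted))
    con <- file(path, "w")
    on.exit(close(con))
    if (comment)
        writeLines(sprintf("# contigDamage %s k=%d",
                           as.character(utils::packageVersion("contigDamage")),
                           if (is.null(fitted)) NA_integer_
                           else ncol(fitted) - 1L),
                   con)
    utils::write.csv(df, con, row.names = FALSE, na = "")
    invisible(path)
}

#' Read a per-contig damage CSV written by [writeDamageCsv()]
#'
#' @param path CSV path (header comment lines starting with \code{#} are
#'   skipped).
#' @return a data.frame.
#' @export
readDamageCsv <- function(path) {
    utils::read.csv(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
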