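# Shared fixture builders: toy SAM writers and an independent brute-force
# recount used as the oracle for the compiled counting kernel.

# Write a SAM file from a records data.frame (qname, flag, rname, pos, mapq,
# cigar, seq, opt) with the given reference lengths.
write_toy_sam <- function(records, targets, path = tempfile(fileext = ".sam")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:coordinate", con)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(targets), targets), con)
    if (nrow(records)) {
        opt <- if (is.null(records$opt)) "" else
            paste0("\t", records$opt)
        writeLines(paste0(records$qname, "\t", records$flag, "\t",
                          records$rname, "\t", records$pos, "\t",
                          records$mapq, "\t", records$cigar,
                          "\t*\t0\t0\t", records$seq, "\t*", opt), con)
    }
    path
}

# Brute-force recount for gap-free (all-match, optionally soft-clipped)
# alignments, written independently of the compiled kernel: splits
# sequences into single characters and walks them in read orientation.
brute_force_counts <- function(reads, refchar, k) {
    N <- M <- integer(k + 1)
    aligned <- 0
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    for (r in seq_len(length(reads$seq))) {
        cig <- reads$cigar[r]
        stopifnot(grepl("^(\\d+S)?\\d+M(\\d+S)?$", cig))
        lead <- ifelse(grepl("^\\d+S", cig),
                       as.integer(sub("S.*", "", cig)), 0L)
        mlen <- as.integer(sub("M.*", "", sub("^\\d+S", "", cig)))
        qs <- strsplit(reads$seq[r], "")[[1]][lead + seq_len(mlen)]
        rs <- strsplit(refchar, "")[[1]][reads$pos[r] + seq_len(mlen) - 1L]
        if (reads$reverse[r]) {       # flip to read orientation
            qs <- rev(unname(comp[qs]))
            rs <- rev(unname(comp[rs]))
        }
        aligned <- aligned + mlen
        for (i in seq_len(min(mlen, k + 1))) {
            if (rs[i] == "C") {
                if (qs[i] == "T") N[i] <- N[i] + 1L
                if (qs[i] == "C") M[i] <- M[i] + 1L
            }
        }
    }
    list(N = N, M = M, aligned = aligned)
}

# Random gap-free toy dataset over a random reference, for property tests.
random_toy_reads <- function(n_reads, ref_len, seed) {
    set.seed(seed)
    ref <- paste(sample(c("A", "C", "G", "T"), ref_len, replace = TRUE),
                 collapse = "")
    width <- sample(5:15, n_reads, replace = TRUE)
    pos <- vapply(width, function(w) sample.int(ref_len - w + 1L, 1L),
                  integer(1))
    reverse <- runif(n_reads) < 0.5
    seq <- substring(ref, pos, pos + width - 1L)
    # random substitutions so both N and M fill up
    for (r in seq_len(n_reads)) {
        nmut <- rbinom(1, width[r], 0.2)
        if (nmut > 0) {
            at <- sample.int(width[r], nmut)
            for (a in at)
                substr(seq[r], a, a) <- sample(c("A", "C", "G", "T"), 1)
        }
    }
    list(reads = list(seq = seq, cigar = paste0(width, "M"), pos = pos,
                      reverse = reverse),
         ref = ref)
}

# Small in-memory TransitionCounts builder for model-level tests.
make_counts <- function(N, M, reflen = 1000, nreads = 100,
                        aligned = NULL) {
    new("TransitionCounts", reference = "toy",
        ctCounts = as.integer(N), ccCounts = as.integer(M),
        nReads = as.integer(nreads), referenceLength = reflen,
        alignedBases = if (is.null(aligned)) sum(N + M) + 100 else aligned)
}
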