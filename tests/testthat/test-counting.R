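test_that("forced substitutions at the 5' end are counted as C->T", {
    reads <- list(seq = "TAAA", cigar = "4M", pos = 1L, reverse = FALSE,
                  md = "0C3")
    tc <- countTransitions(reads, "ctg", 10, k = 3)
    expect_identical(ctCounts(tc), c(1L, 0L, 0L, 0L))
    expect_identical(ccCounts(tc), c(0L, 0L, 0L, 0L))
    expect_identical(nReads(tc), 1L)
    expect_identical(alignedBases(tc), 4)

    # identity read over an all-C reference
    reads <- list(seq = "CCCC", cigar = "4M", pos = 1L, reverse = FALSE,
                  md = "4")
    tc <- countTransitions(reads, "ctg", 10, k = 3)
    expect_identical(ctCounts(tc), c(0L, 0L, 0L, 0L))
    expect_identical(ccCounts(tc), c(1L, 1L, 1L, 1L))
})

test_that("reverse-strand reads are evaluated in read orientation", {
    # rightmost matched column shows reference G read as A; on the reverse
    # strand that column is the read's 5' terminus and complements to C->T.
    # Oracle (by hand): revcomp(ref TTTG) = CAAA, revcomp(read TTTA) = TAAA,
    # so distance 0 carries ref C -> read T.
    reads <- list(seq = "TTTA", cigar = "4M", pos = 1L, reverse = TRUE,
                  md = "3G0")
    tc <- countTransitions(reads, "ctg", 10, k = 3)
    expect_identical(ctCounts(tc), c(1L, 0L, 0L, 0L))
    # same alignment on the forward strand is a G->A at distance 3, invisible
    reads$reverse <- FALSE
    tc <- countTransitions(reads, "ctg", 10, k = 3)
    expect_identical(sum(ctCounts(tc)), 0L)
    expect_identical(sum(ccCounts(tc)), 0L)
})

test_that("FASTA-derived and MD-derived reference bases agree", {
    toy <- random_toy_reads(40, 120, seed = 11)
    md <- character(40)
    for (r in seq_len(40)) {
        w <- nchar(toy$reads$seq[r])
        rs <- substring(toy$ref, toy$reads$pos[r], toy$reads$pos[r] + w - 1L)
        md[r] <- contigDamage:::md_tags_cpp(toy$reads$seq[r], rs)$md
    }
    withMd <- c(toy$reads, list(md = md))
    tcFasta <- countTransitions(toy$reads, "ctg", 120, reference = toy$ref,
                                k = 10)
    tcMd <- countTransitions(withMd, "ctg", 120, k = 10)
    expect_identical(ctCounts(tcFasta), ctCounts(tcMd))
    expect_identical(ccCounts(tcFasta), ccCounts(tcMd))
    expect_error(countTransitions(toy$reads, "ctg", 120, k = 10),
                 "MD tags")
})

test_that("counts match an independent brute-force recount", {
    for (seed in c(1, 2, 3)) {
        toy <- random_toy_reads(60, 150, seed = seed)
        k <- 8
        tc <- countTransitions(toy$reads, "ctg", 150, reference = toy$ref,
                               k = k)
        oracle <- brute_force_counts(toy$reads, toy$ref, k)
        expect_identical(ctCounts(tc), oracle$N)
        expect_identical(ccCounts(tc), oracle$M)
        expect_identical(alignedBases(tc), as.numeric(oracle$aligned))
    }
})

test_that("soft clips are skipped and insertions advance the 5' distance", {
    # 2S3M: clipped TT skipped; alignment starts at ref pos 1 (CCC), read GCC
    reads <- list(seq = "TTGCC", cigar = "2S3M", pos = 1L, reverse = FALSE,
                  md = "0C2")
    tc <- countTransitions(reads, "ctg", 10, reference = "CCCAAA", k = 4)
    expect_identical(ctCounts(tc), integer(5))          # G at distance 0
    expect_identical(ccCounts(tc), c(0L, 1L, 1L, 0L, 0L))
    expect_identical(alignedBases(tc), 3)

    # 1M2I2M over ref "CCC": insertion shifts later matches to distances 3,4
    reads <- list(seq = "TAACC", cigar = "1M2I2M", pos = 1L,
                  reverse = FALSE, md = "0C2")
    tc <- countTransitions(reads, "ctg", 10, reference = "CCCAAA", k = 4)
    expect_identical(ctCounts(tc), c(1L, 0L, 0L, 0L, 0L))
    expect_identical(ccCounts(tc), c(0L, 0L, 0L, 1L, 1L))

    # deletion consumes reference without advancing the read distance
    reads <- list(seq = "CC", cigar = "1M1D1M", pos = 1L, reverse = FALSE,
                  md = "1^A1")
    tc <- countTransitions(reads, "ctg", 10, reference = "CACAAA", k = 4)
    expect_identical(ccCounts(tc)[1:2], c(1L, 1L))
})

test_that("strand symmetry: mirroring the dataset leaves counts unchanged", {
    toy <- random_toy_reads(50, 100, seed = 21)
    k <- 6
    tc <- countTransitions(toy$reads, "ctg", 100, reference = toy$ref, k = k)
    # mirror: reverse-complement the reference, flip strands and coordinates
    rc <- function(s) as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(s)))
    L <- 100L
    w <- nchar(toy$reads$seq)
    mirrored <- list(seq = rc(toy$reads$seq),
                     cigar = toy$reads$cigar,
                     pos = L - (toy$reads$pos + w - 1L) + 1L,
                     reverse = !toy$reads$reverse)
    tcM <- countTransitions(mirrored, "ctg", 100, reference = rc(toy$ref),
                            k = k)
    expect_identical(ctCounts(tcM), ctCounts(tc))
    expect_identical(ccCounts(tcM), ccCounts(tc))
})

test_that("proportions are N/(N+M) with zero denominators flagged missing", {
    tc <- make_counts(N = c(5L, 0L, 0L), M = c(45L, 10L, 0L))
    props <- damageProportions(tc)
    expect_equal(props$pHat, c(0.1, 0, NA))
    expect_identical(props$informative, c(TRUE, TRUE, FALSE))
    expect_true(all(props$pHat >= 0 & props$pHat <= 1, na.rm = TRUE))
})

test_that("coverage is aligned bases over reference length", {
    tc <- make_counts(N = c(0L, 0L), M = c(0L, 0L), reflen = 1000,
                      aligned = 500)
    expect_equal(meanCoverage(tc), 0.5)
    tc0 <- make_counts(N = c(0L, 0L), M = c(0L, 0L), reflen = 1000,
                       nreads = 0, aligned = 0)
    expect_equal(meanCoverage(tc0), 0)
    bad <- make_counts(N = c(0L, 0L), M = c(0L, 0L), reflen = 0, aligned = 0)
    expect_error(meanCoverage(bad), "positive")
})

test_that("simulated coverage lands near its target", {
    spec <- simulationSpec(contigLength = 10000, coverage = 20, damage = 0,
                           seed = 3)
    sim <- simulateContig(spec)
    tc <- countTransitions(
        list(seq = sim$records$seq, cigar = sim$records$cigar,
             pos = sim$records$pos, reverse = sim$records$flag == 16L,
             md = sim$records$md),
        "contig_1", spec$contigLength, k = 35)
    expect_lt(abs(meanCoverage(tc) - 20) / 20, 0.1)
})
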