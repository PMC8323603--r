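#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

// Parser state for an MD tag. MD describes reference bases over the aligned
// reference span: runs of matches (numbers), mismatched reference bases
// (letters), and deleted reference bases (^ACGT...).
struct MDState {
    const char *s;
    int match_run;
    MDState(const char *md) : s(md), match_run(0) {}
    // reference base for the next aligned (M/X/=) column; read_base is the
    // query base at that column (equal to the reference on a match run)
    char next_aligned(char read_base) {
        if (match_run > 0) { --match_run; return read_base; }
        while (*s) {
            if (std::isdigit(*s)) {
                match_run = 0;
                while (std::isdigit(*s)) { match_run = match_run * 10 + (*s - '0'); ++s; }
                if (match_run > 0) { --match_run; return read_base; }
                // zero-length run separates adjacent mismatches; loop on
            } else if (*s == '^') {
                ++s;                       // deletion: handled by skip_deletion
                while (*s && std::isalpha(*s)) ++s;
            } else {
                char ref = std::toupper(*s); ++s;
                return ref;
            }
        }
        return 'N';  // MD exhausted (malformed tag); treated as unknown
    }
    void skip_deletion(int len) {
        // deleted reference bases appear in MD as ^XXX; consume them so that
        // subsequent aligned columns line up
        while (len > 0 && *s) {
            if (std::isdigit(*s)) {
                int run = 0;
                while (std::isdigit(*s)) { run = run * 10 + (*s - '0'); ++s; }
                match_run += run;  // a 0 usually precedes ^
            } else if (*s == '^') {
                ++s;
                while (len > 0 && *s && std::isalpha(*s)) { ++s; --len; }
            } else {
                // mismatch letters should not occur mid-deletion; bail out
                break;
            }
        }
    }
};

// Count 5'-anchored C->T transitions (N) and conserved C->C sites (M) by
// distance i = 0..k from each read's 5' end. Reads on the reverse strand are
// evaluated in read orientation: the distance is counted from the rightmost
// aligned column and the informative pairing is reference G with read A/G on
// the forward reference strand. Distances advance over aligned query columns
// (match/mismatch and insertions); soft clips are skipped. Only
// match/mismatch columns contribute counts.
//
// ref: full reference sequence ("" when absent -> MD tags are required).
// pos is 1-based leftmost mapping position.
// [[Rcpp::export]]
List count_transitions_cpp(CharacterVector seq, CharacterVector cigar,
                           IntegerVector pos, LogicalVector reverse,
                           CharacterVector md, std::string ref, int k) {
    const int n = seq.size();
    const bool use_fasta = !ref.empty();
    IntegerVector N(k + 1), M(k + 1);
    double aligned_bases = 0.0;
    const int ref_len = (int) ref.size();

    for (int r = 0; r < n; ++r) {
        const char *sq = CHAR(STRING_ELT(seq, r));
        const char *cg = CHAR(STRING_ELT(cigar, r));
        const bool rev = reverse[r];
        MDState mdst(md[r] == NA_STRING ? "" : CHAR(STRING_ELT(md, r)));
        if (!use_fasta && md[r] == NA_STRING)
            stop("read %d has no MD tag and no reference FASTA was supplied", r + 1);

        // total aligned query length (M/=/X + I), for reverse-strand distances
        int A = 0;
        {
            const char *c = cg; int len = 0;
            while (*c) {
                if (std::isdigit(*c)) { len = len * 10 + (*c - '0'); }
                else {
                    if (*c == 'M' || *c == '=' || *c == 'X' || *c == 'I') A += len;
                    len = 0;
                }
                ++c;
            }
        }

        int q = 0;                 // index into SEQ (includes soft clips)
        int rp = pos[r] - 1;       // 0-based reference coordinate
        int a = 0;                 // aligned-query index (clip-free)
        const char *c = cg; int len = 0;
        while (*c) {
            if (std::isdigit(*c)) { len = len * 10 + (*c - '0'); ++c; continue; }
            char op = *c; ++c;
            switch (op) {
            case 'M': case '=': case 'X':
                for (int j = 0; j < len; ++j) {
                    char rb;
                    char qb = std::toupper(sq[q]);
                    if (use_fasta) {
                        if (rp < 0 || rp >= ref_len)
                            stop("alignment runs off the reference (pos %d, length %d)",
                                 rp + 1, ref_len);
                        rb = std::toupper(ref[rp]);
                    } else {
                        rb = mdst.next_aligned(qb);
                    }
                    aligned_bases += 1.0;
                    int dist = rev ? (A - 1 - a) : a;
                    if (dist >= 0 && dist <= k) {
                        if (!rev) {
                            if (rb == 'C') {
                                if (qb == 'T') ++N[dist];
                                else if (qb == 'C') ++M[dist];
                            }
                        } else {
                            if (rb == 'G') {
                                if (qb == 'A') ++N[dist];
                                else if (qb == 'G') ++M[dist];
                            }
                        }
                    }
                    ++q; ++rp; ++a;
                }
                break;
            case 'I':
                q += len; a += len;   // inserted bases advance the 5' distance
                break;
            case 'S':
                q += len;             // clipped bases are skipped entirely
                break;
            case 'D': case 'N':
                if (!use_fasta && op == 'D') mdst.skip_deletion(len);
                rp += len;
                break;
            case 'H': case 'P':
                break;
            default:
                stop("unsupported CIGAR operation '%c'", op);
            }
            len = 0;
        }
    }

    return List::create(_["N"] = N, _["M"] = M,
                        _["n_reads"] = n, _["aligned_bases"] = aligned_bases);
}

// MD and NM tags for gap-free (all-match CIGAR) alignments, comparing the
// stored (reference-orientation) read sequence with the reference slice.
// [[Rcpp::export]]
List md_tags_cpp(CharacterVector seq, CharacterVector refslice) {
    const int n = seq.size();
    CharacterVector md(n);
    IntegerVector nm(n);
    std::string buf;
    for (int r = 0; r < n; ++r) {
        const char *sq = CHAR(STRING_ELT(seq, r));
        const char *rf = CHAR(STRING_ELT(refslice, r));
        const int L = (int) LENGTH(STRING_ELT(seq, r));
        buf.clear();
        int run = 0, mism = 0;
        for (int i = 0; i < L; ++i) {
            char qb = std::toupper(sq[i]), rb = std::toupper(rf[i]);
            if (qb == rb) { ++run; }
            else {
                buf += std::to_string(run);
                buf += rb;
                run = 0; ++mism;
            }
        }
        buf += std::to_string(run);
        md[r] = buf;
        nm[r] = mism;
    }
    return List::create(_["md"] = md, _["nm"] = nm);
}
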