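#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// 3' adapter locator. For each read, finds the longest read suffix that
// matches a prefix of the adapter with at least minOverlap nt of overlap
// and at most one substitution per mismWindow nt of overlap (integer
// division). Returns the 0-based trim position (== insert length), or -1
// when no admissible suffix exists. Position 0 means the whole read is
// adapter (adapter dimer).
// [[Rcpp::export]]
IntegerVector locate_adapter_cpp(CharacterVector reads, std::string adapter,
                                 int minOverlap, int mismWindow) {
    int n = reads.size();
    int alen = (int)adapter.size();
    IntegerVector out(n);
    for (int r = 0; r < n; ++r) {
        std::string rd = as<std::string>(reads[r]);
        int len = (int)rd.size();
        int found = -1;
        for (int i = 0; i <= len - minOverlap; ++i) {
            int m = std::min(len - i, alen);
            if (m < minOverlap) break;
            int allowed = m / mismWindow;
            int mm = 0;
            bool ok = true;
            for (int p = 0; p < m; ++p) {
                if (rd[i + p] != adapter[p]) {
                    if (++mm > allowed) { ok = false; break; }
                }
            }
            if (ok) { found = i; break; }
        }
        out[r] = found;
    }
    return out;
}

// Per-read tallies used by the whole-read quality filter: number of bases
// below each of two Phred thresholds, plus whether the sequence contains
// an ambiguous base. Qualities are character-encoded with the given
// offset (33 for Phred+33).
// [[Rcpp::export]]
IntegerMatrix quality_tally_cpp(CharacterVector seqs, CharacterVector quals,
                                int offset, int q1, int q2) {
    int n = seqs.size();
    IntegerMatrix out(n, 3);
    for (int r = 0; r < n; ++r) {
        std::string sq = as<std::string>(seqs[r]);
        std::string ql = as<std::string>(quals[r]);
        if (sq.size() != ql.size())
            stop("sequence and quality lengths differ for read %d", r + 1);
        int c1 = 0, c2 = 0, hasN = 0;
        for (size_t p = 0; p < sq.size(); ++p) {
            int q = (int)ql[p] - offset;
            if (q < q1) ++c1;
            if (q < q2) ++c2;
            char b = sq[p];
            if (b != 'A' && b != 'C' && b != 'G' && b != 'T' &&
                b != 'a' && b != 'c' && b != 'g' && b != 't')
                hasN = 1;
        }
        out(r, 0) = c1;
        out(r, 1) = c2;
        out(r, 2) = hasN;
    }
    return out;
}
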