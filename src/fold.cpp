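#include <Rcpp.h>
#include <vector>
#include <string>
#include <stack>
using namespace Rcpp;

// Base-pair energy lookup. Bases encoded A=0, C=1, G=2, T/U=3.
// Watson-Crick A:U and G:C plus the G:U wobble are the only admissible
// pairs; everything else returns 0 (not pairable).
static inline double pairEnergy(int a, int b, double eGC, double eAU,
                                double eGU) {
    if ((a == 2 && b == 1) || (a == 1 && b == 2)) return eGC;
    if ((a == 0 && b == 3) || (a == 3 && b == 0)) return eAU;
    if ((a == 2 && b == 3) || (a == 3 && b == 2)) return eGU;
    return 0.0; // sentinel: not pairable
}

static inline bool canPair(int a, int b, double eGC, double eAU, double eGU) {
    return pairEnergy(a, b, eGC, eAU, eGU) < 0.0;
}

static int encodeBase(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
    }
}

// Minimum free energy secondary structure by interval dynamic programming
// over stacked base-pair energies (no pseudoknots, hairpin loop >= minloop
// unpaired bases). Ties in energy are resolved toward more base pairs, and
// the traceback prefers pairing the 5'-most base with its 5'-most
// admissible partner, which makes the reported structure deterministic.
// [[Rcpp::export]]
List fold_cpp(std::string seq, double eGC, double eAU, double eGU,
              int minloop) {
    int n = (int)seq.size();
    std::vector<int> s(n);
    for (int i = 0; i < n; ++i) {
        s[i] = encodeBase(seq[i]);
        if (s[i] < 0) stop("invalid character in sequence: '%c'", seq[i]);
    }
    // E[i][j]: minimum energy of subsequence i..j; P[i][j]: max pairs
    // among energy-optimal structures.
    std::vector<std::vector<double> > E(n, std::vector<double>(n, 0.0));
    std::vector<std::vector<int> > P(n, std::vector<int>(n, 0));

    for (int len = 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            // option: i unpaired
            double bestE = E[i + 1][j];
            int bestP = P[i + 1][j];
            // option: pair i with k
            for (int k = i + minloop + 1; k <= j; ++k) {
                if (!canPair(s[i], s[k], eGC, eAU, eGU)) continue;
                double e = pairEnergy(s[i], s[k], eGC, eAU, eGU);
                double inner = (i + 1 <= k - 1) ? E[i + 1][k - 1] : 0.0;
                double right = (k + 1 <= j) ? E[k + 1][j] : 0.0;
                int np = 1 + ((i + 1 <= k - 1) ? P[i + 1][k - 1] : 0) +
                         ((k + 1 <= j) ? P[k + 1][j] : 0);
                double tot = e + inner + right;
                if (tot < bestE - 1e-9 ||
                    (std::abs(tot - bestE) <= 1e-9 && np > bestP)) {
                    bestE = tot;
                    bestP = np;
                }
            }
            E[i][j] = bestE;
            P[i][j] = bestP;
        }
    }

    std::string db(n, '.');
    // traceback, preferring to pair the 5'-most base when optimal
    std::stack<std::pair<int, int> > todo;
    if (n > 1) todo.push(std::make_pair(0, n - 1));
    while (!todo.empty()) {
        int i = todo.top().first, j = todo.top().second;
        todo.pop();
        if (i >= j) continue;
        double target = E[i][j];
        int targetP = P[i][j];
        bool paired = false;
        for (int k = i + minloop + 1; k <= j; ++k) {
            if (!canPair(s[i], s[k], eGC, eAU, eGU)) continue;
            double e = pairEnergy(s[i], s[k], eGC, eAU, eGU);
            double inner = (i + 1 <= k - 1) ? E[i + 1][k - 1] : 0.0;
            double right = (k + 1 <= j) ? E[k + 1][j] : 0.0;
            int np = 1 + ((i + 1 <= k - 1) ? P[i + 1][k - 1] : 0) +
                     ((k + 1 <= j) ? P[k + 1][j] : 0);
            if (std::abs(e + inner + right - target) <= 1e-9 &&
                np == targetP) {
                db[i] = '(';
                db[k] = ')';
                if (i + 1 <= k - 1) todo.push(std::make_pair(i + 1, k - 1));
                if (k + 1 <= j) todo.push(std::make_pair(k + 1, j));
                paired = true;
                break;
            }
        }
        if (!paired) todo.push(std::make_pair(i + 1, j));
    }

    double mfe = (n > 1) ? E[0][n - 1] : 0.0;
    return List::create(_["structure"] = db, _["mfe"] = mfe);
}

// Best ungapped end-to-end match of each tag against a catalog of mature
// sequences. Length differences up to maxShift are absorbed as a terminal
// overhang: the shorter sequence slides along the longer one and
// substitutions are counted over the shorter's full length. Returns, per
// tag, the 1-based index of the best catalog entry (fewest mismatches;
// ties to the earliest entry, so pre-sort the catalog by id) and the
// mismatch count, or index 0 if nothing is within maxMismatch.
// [[Rcpp::export]]
IntegerMatrix match_catalog_cpp(CharacterVector tags,
                                CharacterVector catalog,
                                int maxMismatch, int maxShift) {
    int nt = tags.size(), nc = catalog.size();
    std::vector<std::string> cat(nc);
    for (int c = 0; c < nc; ++c) cat[c] = as<std::string>(catalog[c]);
    IntegerMatrix out(nt, 2);
    for (int t = 0; t < nt; ++t) {
        std::string tag = as<std::string>(tags[t]);
        int bestIdx = 0, bestMm = maxMismatch + 1;
        for (int c = 0; c < nc; ++c) {
            const std::string &m = cat[c];
            int lt = (int)tag.size(), lm = (int)m.size();
            int diff = lt - lm;
            int adiff = diff < 0 ? -diff : diff;
            if (adiff > maxShift) continue;
            const std::string &shorter = (lt <= lm) ? tag : m;
            const std::string &longer = (lt <= lm) ? m : tag;
            int ls = (int)shorter.size();
            for (int off = 0; off <= adiff; ++off) {
                int mm = 0;
                for (int p = 0; p < ls && mm < bestMm; ++p)
                    if (shorter[p] != longer[p + off]) ++mm;
                if (mm < bestMm) {
                    bestMm = mm;
                    bestIdx = c + 1;
                }
            }
        }
        if (bestMm > maxMismatch) { bestIdx = 0; bestMm = NA_INTEGER; }
        out(t, 0) = bestIdx;
        out(t, 1) = bestMm;
    }
    return out;
}
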