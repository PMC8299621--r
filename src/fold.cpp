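#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

// Weighted base-pair-maximization folding (Nussinov-style recursion) used as
// the default secondary-structure stability score. Pair weights GC = -3,
// AU = -2, GU = -1; minimum hairpin loop of 3 unpaired nucleotides, i.e. a
// pair (i, j) requires j - i - 1 >= min_loop.

static inline double pair_weight(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
    if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
    if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
    return 1.0; /* positive => disallowed */
}

// [[Rcpp::export]]
double fold_mfe_dp(std::string seq, int min_loop = 3) {
    const int n = (int) seq.size();
    if (n < 2) return 0.0;
    std::vector<double> E((size_t) n * n, 0.0);
    for (int span = min_loop + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            double best = E[(size_t)(i + 1) * n + j];
            best = std::min(best, E[(size_t) i * n + (j - 1)]);
            double w = pair_weight(seq[i], seq[j]);
            if (w < 0.0)
                best = std::min(best, E[(size_t)(i + 1) * n + (j - 1)] + w);
            for (int k = i; k < j; ++k)
                best = std::min(best, E[(size_t) i * n + k] +
                                      E[(size_t)(k + 1) * n + j]);
            E[(size_t) i * n + j] = best;
        }
    }
    return E[(size_t) 0 * n + (n - 1)];
}
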