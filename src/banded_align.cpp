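#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Banded global (Needleman-Wunsch) alignment of a query against a reference,
// returning only the differences. Intended for near-identical mitogenome
// pairs: the band only needs to cover the cumulative indel offset.
//
// Scoring: match 0, mismatch 1, gap 1 (unit edit costs); ties resolved
// diagonal > up (deletion) > left (insertion) so output is deterministic.
//
// Returns a list with integer vector `type` (1 = mismatch, 2 = insertion
// relative to reference, 3 = deletion from reference), integer `refpos`
// (1-based reference coordinate; for insertions, the base after which the
// inserted base sits), and character `base` (query base for mismatch and
// insertion, reference base for deletion).
// [[Rcpp::export(name = ".bandedAlignDiffs")]]
List bandedAlignDiffs(std::string query, std::string ref, int band) {
    const int n = (int) ref.size();    // rows: reference
    const int m = (int) query.size();  // cols: query
    if (band < 1) band = 1;
    const int W = 2 * band + 1;
    const int INF = std::numeric_limits<int>::max() / 4;

    // dp[i][k] with k = j - i + band, j in [i-band, i+band]
    std::vector<int> prev(W, INF), cur(W, INF);
    // traceback: 0 = diag, 1 = up (gap in query: deletion), 2 = left (insertion)
    std::vector<unsigned char> tb((size_t)(n + 1) * W, 255);

    for (int k = 0; k < W; ++k) {
        int j = 0 - 0 + (k - band); // i = 0 row: j = k - band
        if (j >= 0 && j <= m) prev[k] = j; // all insertions
    }
    for (int i = 1; i <= n; ++i) {
        std::fill(cur.begin(), cur.end(), INF);
        for (int k = 0; k < W; ++k) {
            int j = i + (k - band);
            if (j < 0 || j > m) continue;
            int best = INF; unsigned char dir = 255;
            if (j >= 1) { // diagonal: (i-1, j-1) has same offset k
                int d = prev[k];
                if (d < INF) {
                    int cost = d + (ref[i - 1] == query[j - 1] ||
                                    ref[i - 1] == 'N' || query[j - 1] == 'N' ? 0 : 1);
                    if (cost < best) { best = cost; dir = 0; }
                }
            }
            // up: (i-1, j) -> offset k+1 in prev row
            if (k + 1 < W) {
                int d = prev[k + 1];
                if (d < INF && d + 1 < best) { best = d + 1; dir = 1; }
            }
            // left: (i, j-1) -> offset k-1 in current row
            if (k - 1 >= 0 && j >= 1) {
                int d = cur[k - 1];
                if (d < INF && d + 1 < best) { best = d + 1; dir = 2; }
            }
            cur[k] = best;
            tb[(size_t) i * W + k] = dir;
        }
        std::swap(prev, cur);
    }
    int kEnd = m - n + band;
    if (kEnd < 0 || kEnd >= W || prev[kEnd] >= INF)
        stop("band too narrow for this pair of sequences");

    // traceback from (n, m)
    std::vector<int> type, refpos;
    std::vector<std::string> base;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        int k = j - i + band;
        unsigned char dir = (i == 0) ? 2 : tb[(size_t) i * W + k];
        if (i > 0 && j > 0 && dir == 0) {
            if (ref[i - 1] != query[j - 1] && ref[i - 1] != 'N' && query[j - 1] != 'N') {
                type.push_back(1); refpos.push_back(i);
                base.push_back(std::string(1, query[j - 1]));
            }
            --i; --j;
        } else if (i > 0 && (dir == 1 || j == 0)) {
            type.push_back(3); refpos.push_back(i);
            base.push_back(std::string(1, ref[i - 1]));
            --i;
        } else { // insertion
            type.push_back(2); refpos.push_back(i);
            base.push_back(std::string(1, query[j - 1]));
            --j;
        }
    }
    std::reverse(type.begin(), type.end());
    std::reverse(refpos.begin(), refpos.end());
    std::reverse(base.begin(), base.end());
    return List::create(_["type"] = wrap(type), _["refpos"] = wrap(refpos),
                        _["base"] = wrap(base));
}
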