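#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

// Substitution score. N against anything (including N) is a mismatch: an
// ambiguous base carries no evidence of identity.
static inline int subst(char a, char b, int match, int mismatch) {
    return (a == b && a != 'N') ? match : mismatch;
}

// Local alignment with affine gaps, Gotoh three-state DP.
// Gap cost convention: a gap of length k costs gap_open + k * gap_extend
// (both negative scores), i.e. opening the first gap residue already pays
// gap_open + gap_extend.
//
// States: H = best alignment ending in a residue pair at (i, j);
//         E = ending with a gap in the query row (consumes ref[j]);
//         F = ending with a gap in the ref row (consumes query[i]).
// Tie-breaking (fixed so output is platform-independent):
//   * cell choice: highest H; ties -> smallest (ref_end, query_end);
//   * move choice inside a cell: diagonal > gap-in-ref > gap-in-query;
//   * gap state: prefer closing the gap (shorter gap runs).
// [[Rcpp::export(name = ".gotoh_local")]]
List gotoh_local(std::string query, std::string ref,
                 int match, int mismatch, int gap_open, int gap_extend) {
    const int n = (int) query.size();
    const int m = (int) ref.size();
    const int NEG = INT_MIN / 4;
    const size_t W = (size_t) m + 1;

    std::vector<int> H((size_t)(n + 1) * W, 0);
    std::vector<int> E((size_t)(n + 1) * W, NEG);
    std::vector<int> F((size_t)(n + 1) * W, NEG);
    // pointers: pH 0=stop, 1=diag, 2=F (gap in ref row), 3=E (gap in query row)
    std::vector<unsigned char> pH((size_t)(n + 1) * W, 0);
    std::vector<unsigned char> pE((size_t)(n + 1) * W, 0); // 1 = gap opened here
    std::vector<unsigned char> pF((size_t)(n + 1) * W, 0);

    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            const size_t c = (size_t) i * W + j;
            const size_t up = c - W, lf = c - 1, dg = c - W - 1;

            int e_open = H[lf] + gap_open + gap_extend;
            int e_ext  = (E[lf] <= NEG / 2) ? NEG : E[lf] + gap_extend;
            if (e_open >= e_ext) { E[c] = e_open; pE[c] = 1; }
            else                 { E[c] = e_ext;  pE[c] = 0; }

            int f_open = H[up] + gap_open + gap_extend;
            int f_ext  = (F[up] <= NEG / 2) ? NEG : F[up] + gap_extend;
            if (f_open >= f_ext) { F[c] = f_open; pF[c] = 1; }
            else                 { F[c] = f_ext;  pF[c] = 0; }

            int diag = H[dg] + subst(query[i - 1], ref[j - 1], match, mismatch);
            int h = 0; unsigned char p = 0;
            if (diag >= h && diag > 0)      { h = diag; p = 1; }
            if (F[c] > h)                   { h = F[c]; p = 2; }
            if (E[c] > h)                   { h = E[c]; p = 3; }
            H[c] = h; pH[c] = p;

            if (h > best ||
                (h == best && h > 0 && (j < bj || (j == bj && i < bi)))) {
                best = h; bi = i; bj = j;
            }
        }
    }

    if (best <= 0) {
        return List::create(
            _["aligned_query"] = "", _["aligned_ref"] = "",
            _["score"] = 0,
            _["query_start"] = 0, _["query_end"] = 0,
            _["ref_start"] = 0, _["ref_end"] = 0,
            _["n_match"] = 0, _["n_mismatch"] = 0,
            _["n_gap_columns"] = 0, _["length"] = 0);
    }

    std::string aq, ar;
    int i = bi, j = bj, state = 0; // 0 = H, 2 = F, 3 = E
    int n_match = 0, n_mismatch = 0, n_gap = 0;
    for (;;) {
        const size_t c = (size_t) i * W + j;
        if (state == 0) {
            unsigned char p = pH[c];
            if (p == 0) break;
            if (p == 1) {
                char a = query[i - 1], b = ref[j - 1];
                aq.push_back(a); ar.push_back(b);
                if (a == b && a != 'N') ++n_match; else ++n_mismatch;
                --i; --j;
            } else {
                state = p; // enter gap state at the same cell
            }
        } else if (state == 2) { // gap in ref row, consumes query[i]
            aq.push_back(query[i - 1]); ar.push_back('-'); ++n_gap;
            unsigned char opened = pF[c];
            --i;
            if (opened) state = 0;
        } else { // state == 3: gap in query row, consumes ref[j]
            aq.push_back('-'); ar.push_back(ref[j - 1]); ++n_gap;
            unsigned char opened = pE[c];
            --j;
            if (opened) state = 0;
        }
    }
    std::reverse(aq.begin(), aq.end());
    std::reverse(ar.begin(), ar.end());

    return List::create(
        _["aligned_query"] = aq, _["aligned_ref"] = ar,
        _["score"] = best,
        _["query_start"] = i, _["query_end"] = bi,
        _["ref_start"] = j, _["ref_end"] = bj,
        _["n_match"] = n_match, _["n_mismatch"] = n_mismatch,
        _["n_gap_columns"] = n_gap,
        _["length"] = (int) aq.size());
}

// ---------------------------------------------------------------------------
// Exhaustive reference scorer: recursively enumerates every local alignment
// (every pair of substrings, every interleaving of residue-pair and gap
// columns) and returns the maximum affine-gap score. Exponential by design;
// only usable for short sequences. Kept deliberately independent of the DP
// above so it can act as a validation oracle.
// ---------------------------------------------------------------------------
namespace {
struct EnumCtx {
    const std::string *a, *b;
    int match, mismatch, gap_open, gap_extend;
    long long best;
};

// state: 0 = last column was a residue pair (or alignment start),
//        1 = last column was a gap in b's row, 2 = gap in a's row.
void enum_rec(EnumCtx &ctx, int i, int j, long long sc, int state) {
    if (sc > ctx.best) ctx.best = sc; // the alignment may end here
    const int n = (int) ctx.a->size(), m = (int) ctx.b->size();
    if (i < n && j < m)
        enum_rec(ctx, i + 1, j + 1,
                 sc + subst((*ctx.a)[i], (*ctx.b)[j], ctx.match, ctx.mismatch),
                 0);
    if (i < n)
        enum_rec(ctx, i + 1, j,
                 sc + ctx.gap_extend + (state == 1 ? 0 : ctx.gap_open), 1);
    if (j < m)
        enum_rec(ctx, i, j + 1,
                 sc + ctx.gap_extend + (state == 2 ? 0 : ctx.gap_open), 2);
}
} // namespace

// [[Rcpp::export(name = ".enumerate_local_score")]]
int enumerate_local_score(std::string a, std::string b,
                          int match, int mismatch,
                          int gap_open, int gap_extend) {
    if (a.size() > 10 || b.size() > 10)
        stop("enumerate_local_score is exponential; sequences must be <= 10 nt");
    EnumCtx ctx{&a, &b, match, mismatch, gap_open, gap_extend, 0};
    for (int i = 0; i <= (int) a.size(); ++i)
        for (int j = 0; j <= (int) b.size(); ++j)
            enum_rec(ctx, i, j, 0, 0);
    return (int) ctx.best;
}
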