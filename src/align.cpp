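#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap pairwise alignment over integer-encoded protein sequences.
//
// Encoding: 1-based indices into the rows/cols of `sub` (the substitution
// matrix, typically BLOSUM62 over ARNDCQEGHILKMFPSTWYVX with the X row/column
// zeroed). A gap of length L costs open + (L - 1) * extend, i.e. `open` is
// charged at the first gapped position and `extend` at each additional one.
//
// mode: 0 = local (Smith-Waterman), 1 = global (Needleman-Wunsch, end gaps
// charged).
//
// Tie-breaking is deterministic: in the main state the traceback prefers
// diagonal over up (gap in b) over left (gap in a); among equal-scoring local
// end cells the one with the smallest query index, then subject index, wins.

static const unsigned char PTR_DIAG = 0;
static const unsigned char PTR_UP = 1;   // from F: consumes a, gap in b
static const unsigned char PTR_LEFT = 2; // from E: consumes b, gap in a
static const unsigned char PTR_STOP = 3; // local alignment start

// [[Rcpp::export(name = ".alignPairCpp")]]
List alignPairCpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double open, double extend, int mode) {
    const int n = a.size(), m = b.size();
    const double NEG = -1e30;
    const bool local = (mode == 0);

    // flat copy of the substitution matrix: much cheaper than the Rcpp
    // accessor in the O(n*m) loop
    double smat[21 * 21];
    for (int x = 0; x < 21; ++x)
        for (int y = 0; y < 21; ++y)
            smat[x * 21 + y] = sub(x, y);

    // rolling rows for the scores; full byte matrices for the traceback.
    // H: match state; E: gap in a (left moves); F: gap in b (up moves).
    std::vector<double> Hprev(m + 1), Hcur(m + 1), Fprev(m + 1), Fcur(m + 1);
    std::vector<unsigned char> ptrH((size_t)(n + 1) * (m + 1), PTR_STOP);
    std::vector<unsigned char> ptrE((size_t)(n + 1) * (m + 1), 0);
    std::vector<unsigned char> ptrF((size_t)(n + 1) * (m + 1), 0);

#define IX(i, j) ((size_t)(i) * (m + 1) + (j))

    Hprev[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
        if (local) {
            Hprev[j] = 0.0;
        } else {
            Hprev[j] = -(open + (j - 1) * extend);
            ptrH[IX(0, j)] = PTR_LEFT;
            ptrE[IX(0, j)] = (j == 1) ? 1 : 0;
        }
        Fprev[j] = NEG;
    }
    Fprev[0] = NEG;

    double best = 0.0;
    int bi = 0, bj = 0;
    bool any = false;

    const int *pa = INTEGER(a), *pb = INTEGER(b);
    for (int i = 1; i <= n; ++i) {
        const double *srow = smat + (size_t)(pa[i - 1] - 1) * 21;
        unsigned char *pH = ptrH.data() + IX(i, 0);
        unsigned char *pE = ptrE.data() + IX(i, 0);
        unsigned char *pF = ptrF.data() + IX(i, 0);
        double e = NEG;
        if (local) {
            Hcur[0] = 0.0;
        } else {
            Hcur[0] = -(open + (i - 1) * extend);
            pH[0] = PTR_UP;
            pF[0] = (i == 1) ? 1 : 0;
        }
        Fcur[0] = NEG;
        double hdiag = Hprev[0];  // H[i-1][j-1]
        for (int j = 1; j <= m; ++j) {
            double eOpen = Hcur[j - 1] - open;
            double eExt = e - extend;
            unsigned char pe;
            if (eOpen >= eExt) { e = eOpen; pe = 1; }
            else { e = eExt; pe = 0; }
            pE[j] = pe;

            double fOpen = Hprev[j] - open;
            double fExt = Fprev[j] - extend;
            double f;
            unsigned char pf;
            if (fOpen >= fExt) { f = fOpen; pf = 1; }
            else { f = fExt; pf = 0; }
            Fcur[j] = f;
            pF[j] = pf;

            double h = hdiag + srow[pb[j - 1] - 1];
            unsigned char p = PTR_DIAG;
            if (f > h) { h = f; p = PTR_UP; }
            if (e > h) { h = e; p = PTR_LEFT; }
            if (local && h <= 0.0) { h = 0.0; p = PTR_STOP; }
            hdiag = Hprev[j];
            Hcur[j] = h;
            pH[j] = p;

            if (local && h > best) { best = h; bi = i; bj = j; any = true; }
        }
        std::swap(Hprev, Hcur);
        std::swap(Fprev, Fcur);
    }

    if (!local) {
        best = Hprev[m];
        bi = n; bj = m;
        any = true;
    }

    // Traceback. Aligned columns as residue indices, 0 for gap.
    std::vector<int> outA, outB;
    if (any && !(local && best <= 0.0)) {
        int i = bi, j = bj;
        unsigned char state = 0; // 0=H, 1=E, 2=F
        while (i > 0 || j > 0) {
            if (state == 0) {
                unsigned char p = ptrH[IX(i, j)];
                if (local && p == PTR_STOP) break;
                if (p == PTR_DIAG) {
                    outA.push_back(a[i - 1]);
                    outB.push_back(b[j - 1]);
                    --i; --j;
                } else if (p == PTR_UP) {
                    state = 2;
                } else { // PTR_LEFT
                    state = 1;
                }
            } else if (state == 1) { // E: gap in a, consumes b
                outA.push_back(0);
                outB.push_back(b[j - 1]);
                unsigned char opened = ptrE[IX(i, j)];
                --j;
                if (opened) state = 0;
            } else { // F: gap in b, consumes a
                outA.push_back(a[i - 1]);
                outB.push_back(0);
                unsigned char opened = ptrF[IX(i, j)];
                --i;
                if (opened) state = 0;
            }
            if (local && i == 0 && j == 0) break;
        }
        std::reverse(outA.begin(), outA.end());
        std::reverse(outB.begin(), outB.end());

        // start coordinates (1-based) of the aligned region
        int nA = 0, nB = 0;
        for (size_t k = 0; k < outA.size(); ++k) {
            if (outA[k] > 0) ++nA;
            if (outB[k] > 0) ++nB;
        }
        int aStart = bi - nA + 1, bStart = bj - nB + 1;
        return List::create(_["score"] = best,
                            _["a_aln"] = wrap(outA), _["b_aln"] = wrap(outB),
                            _["a_start"] = aStart, _["a_end"] = bi,
                            _["b_start"] = bStart, _["b_end"] = bj);
    }

    // empty local alignment (all pair scores <= 0)
    return List::create(_["score"] = 0.0,
                        _["a_aln"] = IntegerVector(0), _["b_aln"] = IntegerVector(0),
                        _["a_start"] = NA_INTEGER, _["a_end"] = NA_INTEGER,
                        _["b_start"] = NA_INTEGER, _["b_end"] = NA_INTEGER);
}

// Global affine-gap alignment of two profiles given a precomputed
// column-vs-column score matrix S (ca x cb). Returns the optimal score and the
// merge path: 1 = take a column from both profiles, 2 = column from A only
// (gap in B), 3 = column from B only (gap in A). Same gap cost model and
// tie-break order as alignPairCpp.
// [[Rcpp::export(name = ".alignProfileCpp")]]
List alignProfileCpp(NumericMatrix S, double open, double extend) {
    const int n = S.nrow(), m = S.ncol();
    const double NEG = -1e30;
    std::vector<double> H((n + 1) * (m + 1), NEG);
    std::vector<double> E((n + 1) * (m + 1), NEG);
    std::vector<double> F((n + 1) * (m + 1), NEG);
    std::vector<unsigned char> ptrH((n + 1) * (m + 1), 0);
    std::vector<unsigned char> ptrE((n + 1) * (m + 1), 0);
    std::vector<unsigned char> ptrF((n + 1) * (m + 1), 0);

    H[IX(0, 0)] = 0.0;
    for (int j = 1; j <= m; ++j) {
        E[IX(0, j)] = -(open + (j - 1) * extend);
        H[IX(0, j)] = E[IX(0, j)];
        ptrH[IX(0, j)] = PTR_LEFT;
        ptrE[IX(0, j)] = (j == 1) ? 1 : 0;
    }
    for (int i = 1; i <= n; ++i) {
        F[IX(i, 0)] = -(open + (i - 1) * extend);
        H[IX(i, 0)] = F[IX(i, 0)];
        ptrH[IX(i, 0)] = PTR_UP;
        ptrF[IX(i, 0)] = (i == 1) ? 1 : 0;
    }

    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double eOpen = H[IX(i, j - 1)] - open;
            double eExt = E[IX(i, j - 1)] - extend;
            if (eOpen >= eExt) { E[IX(i, j)] = eOpen; ptrE[IX(i, j)] = 1; }
            else { E[IX(i, j)] = eExt; ptrE[IX(i, j)] = 0; }

            double fOpen = H[IX(i - 1, j)] - open;
            double fExt = F[IX(i - 1, j)] - extend;
            if (fOpen >= fExt) { F[IX(i, j)] = fOpen; ptrF[IX(i, j)] = 1; }
            else { F[IX(i, j)] = fExt; ptrF[IX(i, j)] = 0; }

            double h = H[IX(i - 1, j - 1)] + S(i - 1, j - 1);
            unsigned char p = PTR_DIAG;
            if (F[IX(i, j)] > h) { h = F[IX(i, j)]; p = PTR_UP; }
            if (E[IX(i, j)] > h) { h = E[IX(i, j)]; p = PTR_LEFT; }
            H[IX(i, j)] = h;
            ptrH[IX(i, j)] = p;
        }
    }

    std::vector<int> path;
    int i = n, j = m;
    unsigned char state = 0;
    while (i > 0 || j > 0) {
        if (state == 0) {
            unsigned char p = ptrH[IX(i, j)];
            if (p == PTR_DIAG) { path.push_back(1); --i; --j; }
            else if (p == PTR_UP) state = 2;
            else state = 1;
        } else if (state == 1) {
            path.push_back(3);
            unsigned char opened = ptrE[IX(i, j)];
            --j;
            if (opened) state = 0;
        } else {
            path.push_back(2);
            unsigned char opened = ptrF[IX(i, j)];
            --i;
            if (opened) state = 0;
        }
    }
    std::reverse(path.begin(), path.end());
    return List::create(_["score"] = H[IX(n, m)], _["path"] = wrap(path));
}
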