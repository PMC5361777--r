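#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP), global and local.
//
// Gap convention: a gap of length L costs gapOpen + (L-1)*gapExtend, both
// parameters negative scores (the first gap residue pays the opening).
//
// States: M (a[i] aligned to b[j]), X (gap in b: consumes a, "up"),
//         Y (gap in a: consumes b, "left").
// Tie-break everywhere: diagonal (M) > up (X) > left (Y), so tracebacks are
// bit-stable across platforms and runs.

static const double NEG_INF = -1e18;
static const signed char FROM_M = 0, FROM_X = 1, FROM_Y = 2, START = 3;

struct Cells {
    std::vector<double> M, X, Y;
    std::vector<signed char> pM, pX, pY;
    int ncol;
    Cells(int nr, int nc) : M((size_t)nr * nc, NEG_INF), X((size_t)nr * nc, NEG_INF),
        Y((size_t)nr * nc, NEG_INF), pM((size_t)nr * nc, START), pX((size_t)nr * nc, START),
        pY((size_t)nr * nc, START), ncol(nc) {}
    inline size_t at(int i, int j) const { return (size_t)i * ncol + j; }
    inline double val(int i, int j, int st) const {
        size_t k = at(i, j);
        return st == FROM_M ? M[k] : (st == FROM_X ? X[k] : Y[k]);
    }
    inline signed char ptr(int i, int j, int st) const {
        size_t k = at(i, j);
        return st == FROM_M ? pM[k] : (st == FROM_X ? pX[k] : pY[k]);
    }
};

static inline int best3(double m, double x, double y, double &val) {
    if (m >= x && m >= y) { val = m; return FROM_M; }
    if (x >= y) { val = x; return FROM_X; }
    val = y; return FROM_Y;
}

// [[Rcpp::export(name = ".alignCpp")]]
List alignCpp(std::string a, std::string b, IntegerMatrix sub,
              std::string alphabet, int gapOpen, int gapExtend, bool local) {
    const int n = (int)a.size(), m = (int)b.size();
    if (n < 1 || m < 1) stop("sequences must be non-empty");

    int code[256];
    for (int i = 0; i < 256; ++i) code[i] = -1;
    for (size_t i = 0; i < alphabet.size(); ++i)
        code[(unsigned char)alphabet[i]] = (int)i;
    std::vector<int> ai(n), bj(m);
    for (int i = 0; i < n; ++i) {
        ai[i] = code[(unsigned char)a[i]];
        if (ai[i] < 0) stop("character not in substitution alphabet: '%s'",
                            std::string(1, a[i]).c_str());
    }
    for (int j = 0; j < m; ++j) {
        bj[j] = code[(unsigned char)b[j]];
        if (bj[j] < 0) stop("character not in substitution alphabet: '%s'",
                            std::string(1, b[j]).c_str());
    }

    Cells c(n + 1, m + 1);
    c.M[c.at(0, 0)] = 0.0;
    if (!local) {
        for (int i = 1; i <= n; ++i) {
            c.X[c.at(i, 0)] = gapOpen + (double)(i - 1) * gapExtend;
            c.pX[c.at(i, 0)] = (i == 1) ? FROM_M : FROM_X;
        }
        for (int j = 1; j <= m; ++j) {
            c.Y[c.at(0, j)] = gapOpen + (double)(j - 1) * gapExtend;
            c.pY[c.at(0, j)] = (j == 1) ? FROM_M : FROM_Y;
        }
    } else {
        for (int i = 1; i <= n; ++i) c.M[c.at(i, 0)] = 0.0;
        for (int j = 1; j <= m; ++j) c.M[c.at(0, j)] = 0.0;
    }

    double bestScore = local ? 0.0 : NEG_INF;
    int bestI = 0, bestJ = 0, bestState = FROM_M;

    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            const size_t cur = c.at(i, j), diag = c.at(i - 1, j - 1),
                         up = c.at(i - 1, j), left = c.at(i, j - 1);
            const double s = sub(ai[i - 1], bj[j - 1]);

            double val;
            int st = best3(c.M[diag], c.X[diag], c.Y[diag], val);
            double mval = val + s;
            if (local && mval <= 0.0) {
                c.M[cur] = 0.0;
                c.pM[cur] = START;
            } else {
                c.M[cur] = mval;
                c.pM[cur] = (signed char)st;
            }

            {   // X: gap in b (consumes a[i-1]); opening from M/Y, extension from X
                double fromM = c.M[up] + gapOpen;
                double fromX = c.X[up] + gapExtend;
                double fromY = c.Y[up] + gapOpen;
                if (fromM >= fromX && fromM >= fromY) { c.X[cur] = fromM; c.pX[cur] = FROM_M; }
                else if (fromX >= fromY) { c.X[cur] = fromX; c.pX[cur] = FROM_X; }
                else { c.X[cur] = fromY; c.pX[cur] = FROM_Y; }
            }
            {   // Y: gap in a (consumes b[j-1])
                double fromM = c.M[left] + gapOpen;
                double fromX = c.X[left] + gapOpen;
                double fromY = c.Y[left] + gapExtend;
                if (fromM >= fromX && fromM >= fromY) { c.Y[cur] = fromM; c.pY[cur] = FROM_M; }
                else if (fromX >= fromY) { c.Y[cur] = fromX; c.pY[cur] = FROM_X; }
                else { c.Y[cur] = fromY; c.pY[cur] = FROM_Y; }
            }

            if (local && c.M[cur] > bestScore) {
                bestScore = c.M[cur]; bestI = i; bestJ = j; bestState = FROM_M;
            }
        }
    }

    if (!local) {
        bestState = best3(c.M[c.at(n, m)], c.X[c.at(n, m)], c.Y[c.at(n, m)], bestScore);
        bestI = n; bestJ = m;
    }

    // traceback
    std::string alnA, alnB;
    int i = bestI, j = bestJ, st = bestState;
    int qEnd = bestI, sEnd = bestJ, qStart = bestI, sStart = bestJ;
    bool emptyLocal = local && bestScore <= 0.0;
    if (emptyLocal) {
        qStart = qEnd = sStart = sEnd = 0;
    } else {
        while (true) {
            if (!local && i == 0 && j == 0) break;
            // local alignments start at a zero-reset cell: consume nothing there
            if (local && st == FROM_M && c.pM[c.at(i, j)] == START) break;
            signed char prev = c.ptr(i, j, st);
            if (st == FROM_M) {
                alnA.push_back(a[i - 1]); alnB.push_back(b[j - 1]);
                --i; --j;
            } else if (st == FROM_X) {
                alnA.push_back(a[i - 1]); alnB.push_back('-');
                --i;
            } else {
                alnA.push_back('-'); alnB.push_back(b[j - 1]);
                --j;
            }
            if (prev == START) {
                if (local) break;
                // global START only at (0,0); loop condition handles it
                if (i == 0 && j == 0) break;
            }
            st = prev;
        }
        qStart = i; sStart = j;
        std::reverse(alnA.begin(), alnA.end());
        std::reverse(alnB.begin(), alnB.end());
    }

    const int alignedColumns = (int)alnA.size();
    int matches = 0, gapColumns = 0;
    for (int k = 0; k < alignedColumns; ++k) {
        if (alnA[k] == '-' || alnB[k] == '-') ++gapColumns;
        else if (alnA[k] == alnB[k] && alnA[k] != 'X') ++matches;
    }

    return List::create(
        _["score"] = bestScore,
        _["alignedQuery"] = alnA,
        _["alignedSubject"] = alnB,
        _["alignedColumns"] = alignedColumns,
        _["matches"] = matches,
        _["gapColumns"] = gapColumns,
        _["queryStart"] = qStart,      // 0-based, half-open span [start, end)
        _["queryEnd"] = qEnd,
        _["subjectStart"] = sStart,
        _["subjectEnd"] = sEnd);
}
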