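#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Smith-Waterman with full traceback.
//
// Gap convention: a gap of length k costs gap_open + k * gap_extend
// (the BLAST convention: with open 11 / extend 1 a length-1 gap costs 12).
//
// Determinism: the optimal end cell is the highest-scoring H cell with the
// smallest (i, j); within a cell the traceback prefers diagonal, then a gap
// in the query (E), then a gap in the subject (F).

struct AlnStats {
    int score, columns, idents, mism, gap_opens, gap_cols;
    int qstart, qend, sstart, send;
};

static void encode(const std::string &s, const int *lut, std::vector<int> &out,
                   const char *what) {
    out.resize(s.size());
    for (size_t i = 0; i < s.size(); ++i) {
        out[i] = lut[(unsigned char) s[i]];
        if (out[i] < 0)
            stop("sw_align: residue outside alphabet in %s", what);
    }
}

// workspace reused across calls within one search; traceback packs the H
// pointer (bits 0-1), E-opened flag (bit 2) and F-opened flag (bit 3) into
// one byte per cell
struct SWWork {
    std::vector<int> H, E, F;
    std::vector<unsigned char> tb;
};

static AlnStats sw_core(const std::vector<int> &qi, const std::vector<int> &si,
                        const int *smat, int nr, int gap_open, int gap_extend,
                        SWWork &w) {
    const int m = (int) qi.size();
    const int n = (int) si.size();
    const int NEG = -1000000000;
    const int go = gap_open + gap_extend;
    const int ge = gap_extend;

    w.H.assign(n + 1, 0);
    w.F.assign(n + 1, NEG);
    size_t sz = (size_t)(m + 1) * (n + 1);
    if (w.tb.size() < sz) w.tb.resize(sz);  // fully overwritten row by row

    int best = 0, bi = 0, bj = 0;
    int *H = w.H.data();
    int *F = w.F.data();
    unsigned char *tb = w.tb.data();

    for (int i = 1; i <= m; ++i) {
        const int *srow = smat + qi[i - 1];
        unsigned char *tr = tb + (size_t) i * (n + 1);
        int Hdiag = H[0];  // H(i-1, j-1)
        H[0] = 0;
        int Eprev = NEG;   // E(i, j-1) as we sweep j
        for (int j = 1; j <= n; ++j) {
            // E: gap in query (consumes subject)
            int e_open = H[j - 1] - go;   // H[j-1] already holds row i
            int e_ext = Eprev - ge;
            unsigned char t;
            int e;
            if (e_open >= e_ext) { e = e_open; t = 4; }
            else                 { e = e_ext;  t = 0; }
            // F: gap in subject (consumes query); H[j] still holds row i-1
            int f_open = H[j] - go;
            int f_ext = F[j] - ge;
            int f;
            if (f_open >= f_ext) { f = f_open; t |= 8; }
            else                 { f = f_ext; }
            // H
            int diag = Hdiag + srow[(size_t) si[j - 1] * nr];
            int h = 0;
            if (diag > 0) { h = diag; t |= 1; }
            if (e > h) { h = e; t = (t & 12) | 2; }
            if (f > h) { h = f; t = (t & 12) | 3; }
            Hdiag = H[j];
            H[j] = h;
            Eprev = e;
            F[j] = f;
            tr[j] = t;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }

    AlnStats a = {best, 0, 0, 0, 0, 0, 0, 0, 0, 0};
    if (best == 0) return a;

    int i = bi, j = bj, state = 0;  // 0=H, 1=E, 2=F
    a.qstart = a.qend = bi;
    a.sstart = a.send = bj;
    while (i > 0 && j > 0) {
        unsigned char t = tb[(size_t) i * (n + 1) + j];
        if (state == 0) {
            unsigned char th = t & 3;
            if (th == 0) break;
            if (th == 1) {
                ++a.columns;
                if (qi[i - 1] == si[j - 1]) ++a.idents; else ++a.mism;
                a.qstart = i;
                a.sstart = j;
                --i; --j;
            } else if (th == 2) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) {  // E: gap in query, consume subject
            ++a.columns; ++a.gap_cols;
            a.sstart = j;
            bool opened = (t & 4) != 0;
            --j;
            if (opened) { ++a.gap_opens; state = 0; }
        } else {                  // F: gap in subject, consume query
            ++a.columns; ++a.gap_cols;
            a.qstart = i;
            bool opened = (t & 8) != 0;
            --i;
            if (opened) { ++a.gap_opens; state = 0; }
        }
    }
    return a;
}

static void build_lut(const std::string &alphabet, int *lut) {
    for (int i = 0; i < 256; ++i) lut[i] = -1;
    for (size_t i = 0; i < alphabet.size(); ++i)
        lut[(unsigned char) alphabet[i]] = (int) i;
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string subject,
                  IntegerMatrix score_matrix, std::string alphabet,
                  int gap_open, int gap_extend) {
    if (query.empty() || subject.empty()) stop("sw_align_cpp: empty sequence");
    if (gap_open < 0 || gap_extend <= 0)
        stop("sw_align_cpp: gap penalties must be positive");
    int lut[256];
    build_lut(alphabet, lut);
    std::vector<int> qi, si;
    encode(query, lut, qi, "query");
    encode(subject, lut, si, "subject");
    SWWork w;
    AlnStats a = sw_core(qi, si, &score_matrix[0], score_matrix.nrow(),
                         gap_open, gap_extend, w);
    return List::create(_["score"] = a.score, _["align_length"] = a.columns,
                        _["identities"] = a.idents, _["mismatches"] = a.mism,
                        _["gap_opens"] = a.gap_opens,
                        _["gap_columns"] = a.gap_cols,
                        _["qstart"] = a.qstart, _["qend"] = a.qend,
                        _["sstart"] = a.sstart, _["send"] = a.send);
}

// Batched one-query-vs-many search kernel: one row of alignment statistics
// per subject, avoiding per-pair R call overhead in whole-genome loops.
// [[Rcpp::export]]
NumericMatrix sw_search_cpp(std::string query, CharacterVector subjects,
                            IntegerMatrix score_matrix, std::string alphabet,
                            int gap_open, int gap_extend) {
    if (query.empty()) stop("sw_search_cpp: empty query");
    if (gap_open < 0 || gap_extend <= 0)
        stop("sw_search_cpp: gap penalties must be positive");
    int lut[256];
    build_lut(alphabet, lut);
    std::vector<int> qi, si;
    encode(query, lut, qi, "query");
    const int nsub = subjects.size();
    NumericMatrix out(nsub, 9);
    colnames(out) = CharacterVector::create(
        "score", "align_length", "identities", "mismatches", "gap_opens",
        "qstart", "qend", "sstart", "send");
    SWWork w;
    for (int k = 0; k < nsub; ++k) {
        std::string subj = as<std::string>(subjects[k]);
        if (subj.empty()) stop("sw_search_cpp: empty subject sequence");
        encode(subj, lut, si, "subject");
        AlnStats a = sw_core(qi, si, &score_matrix[0], score_matrix.nrow(),
                             gap_open, gap_extend, w);
        out(k, 0) = a.score;
        out(k, 1) = a.columns;
        out(k, 2) = a.idents;
        out(k, 3) = a.mism;
        out(k, 4) = a.gap_opens;
        out(k, 5) = a.qstart;
        out(k, 6) = a.qend;
        out(k, 7) = a.sstart;
        out(k, 8) = a.send;
    }
    return out;
}
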