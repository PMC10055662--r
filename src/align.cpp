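#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Plain Levenshtein distance, two rolling rows.
static int lev(const std::string &a, const std::string &b) {
    const int n = a.size(), m = b.size();
    if (n == 0) return m;
    if (m == 0) return n;
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        cur[0] = i;
        for (int j = 1; j <= m; ++j) {
            int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

//' Levenshtein edit distance between two strings
//'
//' @param u,v character strings.
//' @return Integer edit distance (unit costs for substitution, insertion,
//'   deletion).
//' @export
// [[Rcpp::export]]
int edit_distance(std::string u, std::string v) {
    return lev(u, v);
}

//' Vectorised edit distance of many strings against one reference
//'
//' @param x character vector.
//' @param ref single reference string.
//' @return Integer vector of edit distances.
//' @export
// [[Rcpp::export]]
IntegerVector edit_distance_to_ref(CharacterVector x, std::string ref) {
    const int n = x.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) out[i] = lev(as<std::string>(x[i]), ref);
    return out;
}

//' Best infix (semi-global) alignment of a pattern inside a text
//'
//' Computes the minimum edit distance between `pattern` and any substring
//' of `text` (gaps at both ends of the text are free), together with the
//' 0-based start and end (half-open) of the best-matching window. Ties are
//' resolved toward the leftmost end position, then the longest window.
//'
//' @param pattern string searched for (e.g. a cell barcode).
//' @param text string searched in (e.g. a softclip region).
//' @return List with `dist`, `start`, `end` (0-based, half-open window).
//' @export
// [[Rcpp::export]]
List infix_edit_distance(std::string pattern, std::string text) {
    const int n = pattern.size(), m = text.size();
    if (n == 0) return List::create(_["dist"] = 0, _["start"] = 0, _["end"] = 0);
    // dp over pattern rows; start[j] tracks origin column of the alignment
    std::vector<int> prev(m + 1), cur(m + 1), sprev(m + 1), scur(m + 1);
    for (int j = 0; j <= m; ++j) { prev[j] = 0; sprev[j] = j; }
    for (int i = 1; i <= n; ++i) {
        cur[0] = i; scur[0] = 0;
        for (int j = 1; j <= m; ++j) {
            int sub = prev[j - 1] + (pattern[i - 1] == text[j - 1] ? 0 : 1);
            int del = prev[j] + 1;      // consume pattern base
            int ins = cur[j - 1] + 1;   // consume text base
            int best = std::min(sub, std::min(del, ins));
            cur[j] = best;
            if (best == sub)      scur[j] = sprev[j - 1];
            else if (best == del) scur[j] = sprev[j];
            else                  scur[j] = scur[j - 1];
        }
        std::swap(prev, cur);
        std::swap(sprev, scur);
    }
    int bestj = 0, bestd = prev[0];
    for (int j = 1; j <= m; ++j) {
        if (prev[j] < bestd) { bestd = prev[j]; bestj = j; }
    }
    return List::create(_["dist"] = bestd,
                        _["start"] = sprev[bestj],
                        _["end"] = bestj);
}

static int nw(const std::string &a, const std::string &b,
              int match, int mismatch, int gap) {
    const int n = a.size(), m = b.size();
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = j * gap;
    for (int i = 1; i <= n; ++i) {
        cur[0] = i * gap;
        for (int j = 1; j <= m; ++j) {
            char x = a[i - 1], y = b[j - 1];
            // N aligns to nothing: always scored as mismatch
            int s = (x == y && x != 'N') ? match : mismatch;
            cur[j] = std::max(prev[j - 1] + s,
                              std::max(prev[j] + gap, cur[j - 1] + gap));
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

//' Needleman-Wunsch global alignment score
//'
//' Global alignment score under a simple linear scheme. `N` bases never
//' match. With the default scheme (+1/-1/-1) the score of two length-L
//' UMIs is `L - 2 * (edits)` for substitution-only differences, so the
//' similarity thresholds used for 10 bp UMI graphs (5 to connect, 7 for a
//' strong edge) correspond to roughly two and one tolerated differences.
//'
//' @param u,v character strings over A,C,G,T,N.
//' @param match,mismatch,gap alignment scores (defaults +1, -1, -1).
//' @return Integer optimal global alignment score.
//' @export
// [[Rcpp::export]]
int nw_score(std::string u, std::string v,
             int match = 1, int mismatch = -1, int gap = -1) {
    return nw(u, v, match, mismatch, gap);
}

//' Pairwise Needleman-Wunsch score matrix
//'
//' @param x character vector of sequences.
//' @param match,mismatch,gap alignment scores.
//' @return Symmetric integer matrix of pairwise global alignment scores;
//'   the diagonal holds self-scores (sequence length under the default
//'   scheme).
//' @export
// [[Rcpp::export]]
IntegerMatrix nw_score_matrix(CharacterVector x,
                              int match = 1, int mismatch = -1, int gap = -1) {
    const int n = x.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
    IntegerMatrix out(n, n);
    for (int i = 0; i < n; ++i) {
        out(i, i) = nw(s[i], s[i], match, mismatch, gap);
        for (int j = i + 1; j < n; ++j) {
            int v = nw(s[i], s[j], match, mismatch, gap);
            out(i, j) = v;
            out(j, i) = v;
        }
    }
    return out;
}

//' Pairwise edit distance matrix
//'
//' @param x character vector of sequences.
//' @return Symmetric integer matrix of Levenshtein distances.
//' @export
// [[Rcpp::export]]
IntegerMatrix edit_distance_matrix(CharacterVector x) {
    const int n = x.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(x[i]);
    IntegerMatrix out(n, n);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            int v = lev(s[i], s[j]);
            out(i, j) = v;
            out(j, i) = v;
        }
    }
    return out;
}
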