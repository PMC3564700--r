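#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Exhaustive-history (LZ76 production) parse.
//
// At each step the longest substring of the already-generated history is
// copied (the copy source may self-overlap, i.e. run past the history
// boundary into symbols written during the current step), then one new
// symbol is appended.  The final component may be a bare copy when the
// input ends mid-copy.
//
// Match search keeps per-character occurrence lists of the history and
// only extends a candidate start when it already matches at the current
// best offset, so typical DNA input runs far below the quadratic worst
// case.
struct LZStep { int start, copy_len, has_add; };

static std::vector<LZStep> lz76_parse(const std::string& str) {
    const char* s = str.c_str();
    const int n = (int)str.size();
    std::vector<LZStep> steps;
    std::vector<int> occ[256];
    int i = 0, filled = 0;
    while (i < n) {
        int best = 0;
        const int maxlen = n - i;
        const unsigned char c0 = (unsigned char)s[i];
        for (int j : occ[c0]) {
            if (best == maxlen) break;
            // candidate must already agree at the current best offset
            if (best > 0 && s[j + best] != s[i + best]) continue;
            int k = 1;
            while (k < maxlen && s[j + k] == s[i + k]) ++k;
            if (k > best) best = k;
        }
        const int has_add = (best < maxlen) ? 1 : 0;
        steps.push_back({i, best, has_add});
        i += best + has_add;
        for (; filled < i; ++filled)
            occ[(unsigned char)s[filled]].push_back(filled);
    }
    return steps;
}

// [[Rcpp::export(name = ".lz_parse_cpp")]]
List lz_parse_cpp(std::string s) {
    if (s.empty()) stop("empty sequence");
    std::vector<LZStep> steps = lz76_parse(s);
    const int m = (int)steps.size();
    IntegerVector start(m), len(m), copy_len(m), has_add(m);
    for (int t = 0; t < m; ++t) {
        start[t] = steps[t].start + 1; // 1-based for R
        copy_len[t] = steps[t].copy_len;
        has_add[t] = steps[t].has_add;
        len[t] = steps[t].copy_len + steps[t].has_add;
    }
    return List::create(
        _["start"] = start, _["length"] = len,
        _["copy_len"] = copy_len, _["has_add"] = has_add);
}

// [[Rcpp::export(name = ".lz_complexity_cpp")]]
int lz_complexity_cpp(std::string s) {
    if (s.empty()) return 0;
    return (int)lz76_parse(s).size();
}

// Complexity of the concatenation s1 + s2 (no separator), avoiding an
// extra copy through R's string pool in the pairwise inner loop.
// [[Rcpp::export(name = ".lz_concat_complexity_cpp")]]
int lz_concat_complexity_cpp(std::string s1, std::string s2) {
    if (s1.empty() || s2.empty()) stop("empty sequence");
    s1 += s2;
    return (int)lz76_parse(s1).size();
}
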