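#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Per-base corruption with substitution / insertion / deletion rates.
// Uses R's RNG so results are reproducible under set.seed().
//
// At each position: an insertion (random base) may be emitted first,
// then the template base is either deleted, substituted by a random
// different base, or copied. A final insertion slot follows the last
// base.
// [[Rcpp::export]]
CharacterVector corrupt_seqs(CharacterVector seqs, double sub_rate,
                             double ins_rate, double del_rate) {
    static const char BASES[4] = {'A', 'C', 'G', 'T'};
    RNGScope rng;
    const int n = seqs.size();
    CharacterVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        std::string r;
        r.reserve(s.size() + 4);
        for (size_t j = 0; j <= s.size(); ++j) {
            if (unif_rand() < ins_rate) {
                r.push_back(BASES[(int)(unif_rand() * 4) % 4]);
            }
            if (j == s.size()) break;
            double u = unif_rand();
            if (u < del_rate) {
                continue;
            } else if (u < del_rate + sub_rate) {
                char b = s[j];
                char nb = b;
                while (nb == b) nb = BASES[(int)(unif_rand() * 4) % 4];
                r.push_back(nb);
            } else {
                r.push_back(s[j]);
            }
        }
        out[i] = r;
    }
    return out;
}
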