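// Island-model simulator with sex-specific migration, used to predict
// uniparental haplotype diversity under different residence regimes.
// Non-overlapping generations; fixed deme sizes restored each generation;
// migration (uniform destination != origin) precedes random monogamous
// within-deme pairing. mtDNA labels follow mothers, Y labels fathers.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static void migrate(std::vector<int>& deme, double m, int nDemes) {
    if (m <= 0 || nDemes < 2) return;
    for (std::size_t i = 0; i < deme.size(); ++i)
        if (unif_rand() < m) {
            int d = (int)(unif_rand() * (nDemes - 1));
            if (d >= deme[i]) ++d;
            deme[i] = d;
        }
}

static void shuffle(std::vector<int>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        std::swap(v[i], v[j]);
    }
}

// Runs one replicate; returns success flag plus the final generation's
// labels (integers indexing the founding haplotypes). A deme emptied of one
// sex flags the replicate as failed so the caller can resample it.
// [[Rcpp::export]]
List cpp_deme_replicate(int nDemes, int nF, int nM, double mF, double mM,
                        int gens) {
    int NF = nDemes * nF, NM = nDemes * nM;
    std::vector<int> mtF(NF), mtM(NM), yM(NM), dF(NF), dM(NM);
    for (int i = 0; i < NF; ++i) { mtF[i] = i; dF[i] = i / nF; }
    for (int i = 0; i < NM; ++i) { mtM[i] = NF + i; yM[i] = i; dM[i] = i / nM; }
    std::vector<std::vector<int> > fIdx(nDemes), mIdx(nDemes);
    for (int g = 0; g < gens; ++g) {
        migrate(dF, mF, nDemes);
        migrate(dM, mM, nDemes);
        for (int d = 0; d < nDemes; ++d) { fIdx[d].clear(); mIdx[d].clear(); }
        for (int i = 0; i < NF; ++i) fIdx[dF[i]].push_back(i);
        for (int i = 0; i < NM; ++i) mIdx[dM[i]].push_back(i);
        for (int d = 0; d < nDemes; ++d)
            if (fIdx[d].empty() || mIdx[d].empty())
                return List::create(_["ok"] = false);
        std::vector<int> nmtF(NF), nmtM(NM), nyM(NM);
        for (int d = 0; d < nDemes; ++d) {
            shuffle(fIdx[d]);
            shuffle(mIdx[d]);
            int k = (int)std::min(fIdx[d].size(), mIdx[d].size());
            for (int s = 0; s < nF; ++s) {
                int r = (int)(unif_rand() * k);
                nmtF[d * nF + s] = mtF[fIdx[d][r]];
            }
            for (int s = 0; s < nM; ++s) {
                int r = (int)(unif_rand() * k);
                nmtM[d * nM + s] = mtF[fIdx[d][r]];
                nyM[d * nM + s] = yM[mIdx[d][r]];
            }
        }
        mtF.swap(nmtF); mtM.swap(nmtM); yM.swap(nyM);
        for (int i = 0; i < NF; ++i) dF[i] = i / nF;
        for (int i = 0; i < NM; ++i) dM[i] = i / nM;
    }
    return List::create(_["ok"] = true, _["mtF"] = mtF, _["mtM"] = mtM,
                        _["yM"] = yM);
}
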