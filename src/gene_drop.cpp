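// Gene dropping through fixed pedigrees and founder-segment IBD extraction.
// Haplotypes are stored as breakpoint vectors: segment i spans
// [end[i-1] (or 0), end[i]) in cM and carries founder allele fid[i].
// All randomness comes from R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Hap {
    std::vector<double> end;
    std::vector<int> fid;
};

static Hap founderHap(double len, int id) {
    Hap h;
    h.end.push_back(len);
    h.fid.push_back(id);
    return h;
}

// One meiosis: Poisson(len/100) crossovers at uniform positions, random
// starting phase, no interference.
static Hap meiosis(const Hap& A, const Hap& B, double len) {
    int k = (int) R::rpois(len / 100.0);
    std::vector<double> xs(k);
    for (int i = 0; i < k; ++i) xs[i] = unif_rand() * len;
    std::sort(xs.begin(), xs.end());
    const Hap* H[2] = { &A, &B };
    std::size_t idx[2] = { 0, 0 };
    int c = (unif_rand() < 0.5) ? 0 : 1;
    Hap out;
    double pos = 0.0;
    std::size_t ix = 0;
    while (pos < len - 1e-12) {
        while (H[c]->end[idx[c]] <= pos + 1e-15) ++idx[c];
        double segEnd = H[c]->end[idx[c]];
        double nx = (ix < xs.size()) ? xs[ix] : len;
        double bound = std::min(segEnd, nx);
        if (bound > pos + 1e-15) {
            int f = H[c]->fid[idx[c]];
            if (!out.fid.empty() && out.fid.back() == f) out.end.back() = bound;
            else { out.end.push_back(bound); out.fid.push_back(f); }
        }
        pos = bound;
        if (ix < xs.size() && nx <= segEnd) { c = 1 - c; ++ix; }
    }
    if (!out.end.empty()) out.end.back() = len;
    return out;
}

struct Genome {
    std::vector<std::array<Hap, 2> > autos;
    Hap x[2];
    int nx;
};

// mother/father are 0-based indices into the pedigree (parents must precede
// children); -1 marks founders. Founder i carries allele ids 2i and 2i+1.
static void dropAll(const IntegerVector& mother, const IntegerVector& father,
                    const LogicalVector& male, const NumericVector& chromLens,
                    double xLen, std::vector<Genome>& G) {
    int n = mother.size(), K = chromLens.size();
    G.assign(n, Genome());
    for (int i = 0; i < n; ++i) {
        G[i].autos.resize(K);
        if (mother[i] < 0) {
            for (int c = 0; c < K; ++c) {
                G[i].autos[c][0] = founderHap(chromLens[c], 2 * i);
                G[i].autos[c][1] = founderHap(chromLens[c], 2 * i + 1);
            }
            if (male[i]) {
                G[i].nx = 1;
                G[i].x[0] = founderHap(xLen, 2 * i);
            } else {
                G[i].nx = 2;
                G[i].x[0] = founderHap(xLen, 2 * i);
                G[i].x[1] = founderHap(xLen, 2 * i + 1);
            }
        } else {
            int mo = mother[i], fa = father[i];
            for (int c = 0; c < K; ++c) {
                G[i].autos[c][0] = meiosis(G[mo].autos[c][0], G[mo].autos[c][1],
                                           chromLens[c]);
                G[i].autos[c][1] = meiosis(G[fa].autos[c][0], G[fa].autos[c][1],
                                           chromLens[c]);
            }
            G[i].x[0] = meiosis(G[mo].x[0], G[mo].x[G[mo].nx > 1 ? 1 : 0], xLen);
            if (male[i]) {
                G[i].nx = 1;             // no father-to-son X transmission
            } else {
                G[i].nx = 2;
                G[i].x[1] = G[fa].x[0];  // father's X passed intact
            }
        }
    }
}

// [[Rcpp::export]]
List cpp_drop_genomes(IntegerVector mother, IntegerVector father,
                      LogicalVector male, NumericVector chromLens,
                      double xLen) {
    std::vector<Genome> G;
    dropAll(mother, father, male, chromLens, xLen, G);
    int n = mother.size(), K = chromLens.size();
    std::vector<int> ind, hap, chrom, fid;
    std::vector<double> st, en;
    for (int i = 0; i < n; ++i) {
        for (int c = 0; c < K; ++c)
            for (int h = 0; h < 2; ++h) {
                const Hap& H = G[i].autos[c][h];
                double s = 0.0;
                for (std::size_t s2 = 0; s2 < H.end.size(); ++s2) {
                    ind.push_back(i + 1); hap.push_back(h + 1);
                    chrom.push_back(c + 1); fid.push_back(H.fid[s2]);
                    st.push_back(s); en.push_back(H.end[s2]);
                    s = H.end[s2];
                }
            }
        for (int h = 0; h < G[i].nx; ++h) {
            const Hap& H = G[i].x[h];
            double s = 0.0;
            for (std::size_t s2 = 0; s2 < H.end.size(); ++s2) {
                ind.push_back(i + 1); hap.push_back(h + 1);
                chrom.push_back(K + 1); fid.push_back(H.fid[s2]);
                st.push_back(s); en.push_back(H.end[s2]);
                s = H.end[s2];
            }
        }
    }
    return List::create(_["ind"] = ind, _["hap"] = hap, _["chrom"] = chrom,
                        _["start"] = st, _["end"] = en, _["founder"] = fid);
}

struct Seg { double s, e; int f; };

// Maximal runs where two segment lists carry the same founder allele.
static void sharedRuns(const std::vector<Seg>& A, const std::vector<Seg>& B,
                       std::vector<Seg>& out) {
    std::size_t ia = 0, ib = 0;
    while (ia < A.size() && ib < B.size()) {
        double lo = std::max(A[ia].s, B[ib].s);
        double hi = std::min(A[ia].e, B[ib].e);
        if (hi > lo + 1e-12 && A[ia].f == B[ib].f) {
            if (!out.empty() && out.back().f == A[ia].f &&
                lo <= out.back().e + 1e-9)
                out.back().e = std::max(out.back().e, hi);
            else
                out.push_back(Seg{ lo, hi, A[ia].f });
        }
        if (A[ia].e < B[ib].e) ++ia; else ++ib;
    }
}

// [[Rcpp::export]]
List cpp_ibd_from_paths(IntegerVector ind, IntegerVector hap,
                        IntegerVector chrom, NumericVector start,
                        NumericVector end, IntegerVector founder,
                        double minCm) {
    // group segments by (chrom, ind, hap)
    int n = ind.size();
    int maxC = 0;
    for (int i = 0; i < n; ++i) maxC = std::max(maxC, chrom[i]);
    std::vector<int> oInd, oH1, oInd2, oH2, oChrom;
    std::vector<double> oS, oE;
    for (int c = 1; c <= maxC; ++c) {
        // collect haplotype keys present on this chromosome
        std::vector<std::pair<int, int> > keys;
        std::vector<std::vector<Seg> > segs;
        for (int i = 0; i < n; ++i) {
            if (chrom[i] != c) continue;
            std::pair<int, int> k(ind[i], hap[i]);
            std::size_t j = 0;
            for (; j < keys.size(); ++j) if (keys[j] == k) break;
            if (j == keys.size()) { keys.push_back(k); segs.push_back({}); }
            segs[j].push_back(Seg{ start[i], end[i], founder[i] });
        }
        for (auto& v : segs)
            std::sort(v.begin(), v.end(),
                      [](const Seg& a, const Seg& b) { return a.s < b.s; });
        // deterministic ordering of haplotypes
        std::vector<std::size_t> ord(keys.size());
        for (std::size_t i = 0; i < ord.size(); ++i) ord[i] = i;
        std::sort(ord.begin(), ord.end(), [&](std::size_t a, std::size_t b) {
            return keys[a] < keys[b];
        });
        for (std::size_t a = 0; a < ord.size(); ++a)
            for (std::size_t b = a + 1; b < ord.size(); ++b) {
                const std::pair<int, int>& ka = keys[ord[a]];
                const std::pair<int, int>& kb = keys[ord[b]];
                std::vector<Seg> runs;
                sharedRuns(segs[ord[a]], segs[ord[b]], runs);
                for (const Seg& r : runs)
                    if (r.e - r.s >= minCm) {
                        oInd.push_back(ka.first); oH1.push_back(ka.second);
                        oInd2.push_back(kb.first); oH2.push_back(kb.second);
                        oChrom.push_back(c);
                        oS.push_back(r.s); oE.push_back(r.e);
                    }
            }
    }
    return List::create(_["ind1"] = oInd, _["hap1"] = oH1, _["ind2"] = oInd2,
                        _["hap2"] = oH2, _["chrom"] = oChrom, _["start"] = oS,
                        _["end"] = oE);
}

static double runLen(const std::vector<Seg>& v) {
    double t = 0;
    for (const Seg& s : v) t += s.e - s.s;
    return t;
}

// union of two lists of disjoint sorted intervals
static std::vector<Seg> unionIv(const std::vector<Seg>& A,
                                const std::vector<Seg>& B) {
    std::vector<Seg> all = A;
    all.insert(all.end(), B.begin(), B.end());
    std::sort(all.begin(), all.end(),
              [](const Seg& a, const Seg& b) { return a.s < b.s; });
    std::vector<Seg> out;
    for (const Seg& s : all) {
        if (!out.empty() && s.s <= out.back().e + 1e-9)
            out.back().e = std::max(out.back().e, s.e);
        else out.push_back(s);
    }
    return out;
}

static double intersectLen(const std::vector<Seg>& A,
                           const std::vector<Seg>& B) {
    double t = 0;
    std::size_t ia = 0, ib = 0;
    while (ia < A.size() && ib < B.size()) {
        double lo = std::max(A[ia].s, B[ib].s);
        double hi = std::min(A[ia].e, B[ib].e);
        if (hi > lo) t += hi - lo;
        if (A[ia].e < B[ib].e) ++ia; else ++ib;
    }
    return t;
}

static std::vector<Seg> hapSegs(const Hap& H) {
    std::vector<Seg> v;
    double s = 0;
    for (std::size_t i = 0; i < H.end.size(); ++i) {
        v.push_back(Seg{ s, H.end[i], H.fid[i] });
        s = H.end[i];
    }
    return v;
}

// Realized autosomal kinship, IBD1/IBD2 fractions and X kinship for a set of
// pairs over repeated gene drops. Rows = replicates, columns = pairs.
// [[Rcpp::export]]
List cpp_replicate_kinship(IntegerVector mother, IntegerVector father,
                           LogicalVector male, NumericVector chromLens,
                           double xLen, IntegerVector pairA,
                           IntegerVector pairB, int nReps) {
    int nP = pairA.size(), K = chromLens.size();
    double L = 0;
    for (int c = 0; c < K; ++c) L += chromLens[c];
    NumericMatrix phi(nReps, nP), f1(nReps, nP), f2(nReps, nP),
        phiX(nReps, nP);
    std::vector<Genome> G;
    for (int r = 0; r < nReps; ++r) {
        dropAll(mother, father, male, chromLens, xLen, G);
        for (int p = 0; p < nP; ++p) {
            int a = pairA[p], b = pairB[p];
            double tot = 0, u1 = 0, u2 = 0, i2 = 0, xshare = 0;
            for (int c = 0; c < K; ++c) {
                std::vector<Seg> ch[2][2];
                for (int i = 0; i < 2; ++i) {
                    std::vector<Seg> sa = hapSegs(G[a].autos[c][i]);
                    for (int j = 0; j < 2; ++j) {
                        std::vector<Seg> sb = hapSegs(G[b].autos[c][j]);
                        sharedRuns(sa, sb, ch[i][j]);
                        tot += runLen(ch[i][j]);
                    }
                }
                std::vector<Seg> U1 = unionIv(ch[0][0], ch[0][1]);
                std::vector<Seg> U2 = unionIv(ch[1][0], ch[1][1]);
                u1 += runLen(U1); u2 += runLen(U2);
                i2 += intersectLen(U1, U2);
            }
            phi(r, p) = tot / (4.0 * L);
            f2(r, p) = i2 / L;
            f1(r, p) = (u1 + u2 - 2.0 * i2) / L;
            int na = G[a].nx, nb = G[b].nx;
            for (int i = 0; i < na; ++i) {
                std::vector<Seg> sa = hapSegs(G[a].x[i]);
                for (int j = 0; j < nb; ++j) {
                    std::vector<Seg> sb = hapSegs(G[b].x[j]);
                    std::vector<Seg> runs;
                    sharedRuns(sa, sb, runs);
                    xshare += runLen(runs);
                }
            }
            phiX(r, p) = xshare / (na * nb * xLen);
        }
    }
    return List::create(_["phi"] = phi, _["f1"] = f1, _["f2"] = f2,
                        _["phiX"] = phiX);
}
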