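// Tract-based Wright-Fisher engine for admixed populations.
//
// A haplotype is a run-length encoding of ancestry along one chromosome in
// genetic-map units: strictly increasing tract end positions (cM, last equals
// the chromosome length) plus one ancestry label per tract (1 = minor parent,
// 0 = major parent).  Crossovers are placed uniformly in cM with a per-meiosis
// count ~ Poisson(L/100), i.e. map-based recombination with no interference.
//
// All randomness flows through R's RNG so set.seed() on the R side makes runs
// reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Hap {
    std::vector<double> ends;
    std::vector<unsigned char> anc;
};

static inline void push_tract(Hap &out, double end, unsigned char a) {
    if (!out.anc.empty() && out.anc.back() == a)
        out.ends.back() = end;
    else {
        out.ends.push_back(end);
        out.anc.push_back(a);
    }
}

// Append the piece of H covering [a, b) to out (canonical: merges neighbours).
static void copy_interval(const Hap &H, double a, double b, Hap &out) {
    if (b <= a) return;
    size_t i = std::upper_bound(H.ends.begin(), H.ends.end(), a) - H.ends.begin();
    if (i >= H.ends.size()) i = H.ends.size() - 1;  // numeric guard at L
    for (; i < H.ends.size(); ++i) {
        double e = std::min(H.ends[i], b);
        push_tract(out, e, H.anc[i]);
        if (H.ends[i] >= b) break;
    }
}

// Ancestry (0/1) of H at position p; tract i covers (ends[i-1], ends[i]].
// p = 0 falls in the first tract.
static inline int anc_at(const Hap &H, double p) {
    size_t i = std::lower_bound(H.ends.begin(), H.ends.end(), p) - H.ends.begin();
    if (i >= H.ends.size()) i = H.ends.size() - 1;
    return H.anc[i];
}

// Writes the gamete into `out`, reusing its buffers across generations.
static void make_gamete(const Hap &A, const Hap &B, double L, Hap &out,
                        std::vector<double> &xs) {
    int k = (int) R::rpois(L / 100.0);
    xs.clear();
    for (int j = 0; j < k; ++j) xs.push_back(L * unif_rand());
    std::sort(xs.begin(), xs.end());
    xs.push_back(L);
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    out.ends.clear();
    out.anc.clear();
    double pos = 0.0;
    for (double x : xs) {
        if (x > pos) {
            copy_interval(cur ? B : A, pos, x, out);
            pos = x;
        }
        cur ^= 1;
    }
}

static Hap pure_hap(double L, unsigned char a) {
    Hap h;
    h.ends.push_back(L);
    h.anc.push_back(a);
    return h;
}

// Population: pop[c][2*i + h] = haplotype h of individual i on chromosome c.
typedef std::vector<std::vector<Hap> > Pop;

// Dominance interpolation f(0)=0, f(1)=h, f(2)=1 on a dosage in {0,1,2}.
static inline double dom_f(int dosage, double h) {
    return dosage == 0 ? 0.0 : (dosage == 1 ? h : 1.0);
}

// sel_mode: 0 neutral, 1 dmi_pairs, 2 hybridization_load, 3 single_parent.
// sel_loci columns (dmi): chr1, cm1, chr2, cm2, s, h.
// sel_loci columns (load/single_parent): chr, cm, s, h, target
//   target = 1 selection acts on minor-parent dosage, 0 on major-parent dosage.
static void fitness_vec(const Pop &pop, int N, int sel_mode,
                        const NumericMatrix &sel_loci, std::vector<double> &w) {
    std::fill(w.begin(), w.end(), 1.0);
    if (sel_mode == 0) return;
    for (int i = 0; i < N; ++i) {
        double fit = 1.0;
        for (int r = 0; r < sel_loci.nrow(); ++r) {
            if (sel_mode == 1) {
                int c1 = (int) sel_loci(r, 0), c2 = (int) sel_loci(r, 2);
                double p1 = sel_loci(r, 1), p2 = sel_loci(r, 3);
                double s = sel_loci(r, 4), h = sel_loci(r, 5);
                int a = anc_at(pop[c1][2 * i], p1) + anc_at(pop[c1][2 * i + 1], p1);
                int bmin = anc_at(pop[c2][2 * i], p2) + anc_at(pop[c2][2 * i + 1], p2);
                int b = 2 - bmin;  // major-parent dosage at the partner locus
                fit *= 1.0 - s * dom_f(a, h) * dom_f(b, h);
            } else {
                int c = (int) sel_loci(r, 0);
                double p = sel_loci(r, 1), s = sel_loci(r, 2), h = sel_loci(r, 3);
                int target = (int) sel_loci(r, 4);
                int dmin = anc_at(pop[c][2 * i], p) + anc_at(pop[c][2 * i + 1], p);
                int d = target == 1 ? dmin : 2 - dmin;
                fit *= 1.0 - s * dom_f(d, h);
            }
        }
        if (fit < 0.0) fit = 0.0;
        w[i] = fit;
    }
}

static int sample_weighted(const std::vector<double> &cw) {
    double u = unif_rand() * cw.back();
    return (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
}

// [[Rcpp::export(name = ".wf_simulate_cpp")]]
List wf_simulate_cpp(NumericVector chr_len_cM, int N, int T, double m0,
                     double mig_minor, double mig_major, int sel_mode,
                     NumericMatrix sel_loci, IntegerVector marker_chr,
                     NumericVector marker_cM, bool return_matrix,
                     bool return_site_freq, bool return_tracts) {
    int C = chr_len_cM.size();
    int M = marker_cM.size();
    RNGScope scope;

    Pop pop(C), next(C);
    std::vector<unsigned char> founder(N);
    for (int i = 0; i < N; ++i) founder[i] = unif_rand() < m0 ? 1 : 0;
    for (int c = 0; c < C; ++c) {
        pop[c].resize(2 * N);
        next[c].resize(2 * N);
        for (int i = 0; i < N; ++i) {
            pop[c][2 * i] = pure_hap(chr_len_cM[c], founder[i]);
            pop[c][2 * i + 1] = pure_hap(chr_len_cM[c], founder[i]);
        }
    }

    std::vector<double> w(N), cw(N);
    std::vector<double> xbuf;
    for (int t = 0; t < T; ++t) {
        // Migration: replace a Binomial(N, mig) subset with pure parentals,
        // before fitness evaluation and reproduction.
        for (int side = 0; side < 2; ++side) {
            double mig = side == 0 ? mig_minor : mig_major;
            if (mig <= 0.0) continue;
            int nmig = (int) R::rbinom((double) N, mig);
            for (int j = 0; j < nmig; ++j) {
                int i = (int)(unif_rand() * N);
                if (i >= N) i = N - 1;
                for (int c = 0; c < C; ++c) {
                    pop[c][2 * i] = pure_hap(chr_len_cM[c], side == 0 ? 1 : 0);
                    pop[c][2 * i + 1] = pure_hap(chr_len_cM[c], side == 0 ? 1 : 0);
                }
            }
        }
        fitness_vec(pop, N, sel_mode, sel_loci, w);
        double tot = 0.0;
        for (int i = 0; i < N; ++i) { tot += w[i]; cw[i] = tot; }
        if (tot <= 0.0) stop("all individuals have zero fitness in generation %d", t + 1);
        for (int i = 0; i < N; ++i) {
            int mom = sample_weighted(cw);
            int dad = sample_weighted(cw);
            for (int c = 0; c < C; ++c) {
                make_gamete(pop[c][2 * mom], pop[c][2 * mom + 1], chr_len_cM[c],
                            next[c][2 * i], xbuf);
                make_gamete(pop[c][2 * dad], pop[c][2 * dad + 1], chr_len_cM[c],
                            next[c][2 * i + 1], xbuf);
            }
        }
        std::swap(pop, next);
        if (t % 16 == 0) Rcpp::checkUserInterrupt();
    }

    List out;

    // Dosage at markers (marker_chr is 0-based chromosome index; marker_cM
    // must be sorted within chromosome).
    if (return_matrix || return_site_freq) {
        IntegerMatrix geno;
        std::vector<double> freq(M, 0.0);
        if (return_matrix) geno = IntegerMatrix(N, M);
        for (int i = 0; i < N; ++i) {
            for (int c = 0, j0 = 0; c < C; ++c) {
                const Hap &h1 = pop[c][2 * i], &h2 = pop[c][2 * i + 1];
                size_t i1 = 0, i2 = 0;
                for (int j = j0; j < M && marker_chr[j] == c; ++j) {
                    double p = marker_cM[j];
                    while (i1 + 1 < h1.ends.size() && h1.ends[i1] < p) ++i1;
                    while (i2 + 1 < h2.ends.size() && h2.ends[i2] < p) ++i2;
                    int d = h1.anc[i1] + h2.anc[i2];
                    if (return_matrix) geno(i, j) = d;
                    freq[j] += d;
                }
                while (j0 < M && marker_chr[j0] == c) ++j0;
            }
        }
        if (return_matrix) out["dosage"] = geno;
        if (return_site_freq) {
            NumericVector sf(M);
            for (int j = 0; j < M; ++j) sf[j] = freq[j] / (2.0 * N);
            out["site_freq"] = sf;
        }
    }

    // Engine-side summary statistics (tract-based): median minor tract
    // length, mean hybrid index, mean over chromosomes of the CV across
    // individuals of chromosome-wide minor ancestry.
    {
        std::vector<double> minor_lens;
        double hi_sum = 0.0;
        double tot_cM = 0.0;
        for (int c = 0; c < C; ++c) tot_cM += chr_len_cM[c];
        std::vector<std::vector<double> > chrom_anc(C, std::vector<double>(N, 0.0));
        for (int i = 0; i < N; ++i) {
            double minor_cM = 0.0;
            for (int c = 0; c < C; ++c) {
                for (int hh = 0; hh < 2; ++hh) {
                    const Hap &H = pop[c][2 * i + hh];
                    double prev = 0.0;
                    for (size_t k = 0; k < H.ends.size(); ++k) {
                        double len = H.ends[k] - prev;
                        if (H.anc[k] == 1) {
                            minor_lens.push_back(len);
                            minor_cM += len;
                            chrom_anc[c][i] += len;
                        }
                        prev = H.ends[k];
                    }
                }
            }
            hi_sum += minor_cM / (2.0 * tot_cM);
        }
        double med = NA_REAL;
        if (!minor_lens.empty()) {
            size_t n = minor_lens.size();
            std::sort(minor_lens.begin(), minor_lens.end());
            med = (n % 2 == 1) ? minor_lens[n / 2]
                               : 0.5 * (minor_lens[n / 2 - 1] + minor_lens[n / 2]);
        }
        double cv_sum = 0.0;
        int cv_n = 0;
        for (int c = 0; c < C; ++c) {
            double m = 0.0, ss = 0.0;
            for (int i = 0; i < N; ++i) m += chrom_anc[c][i];
            m /= N;
            for (int i = 0; i < N; ++i) {
                double d = chrom_anc[c][i] - m;
                ss += d * d;
            }
            double sd = std::sqrt(ss / (N - 1));
            if (m > 0.0) { cv_sum += sd / m; ++cv_n; }
        }
        out["stats"] = NumericVector::create(
            _["median_minor_tract_cM"] = med,
            _["mean_hybrid_index"] = hi_sum / N,
            _["cv_chrom_ancestry"] = cv_n > 0 ? cv_sum / cv_n : NA_REAL);
    }

    if (return_tracts) {
        size_t nrow = 0;
        for (int c = 0; c < C; ++c)
            for (int i = 0; i < 2 * N; ++i) nrow += pop[c][i].ends.size();
        IntegerVector ind(nrow), hap(nrow), chrom(nrow), anc(nrow);
        NumericVector start(nrow), end(nrow);
        size_t r = 0;
        for (int i = 0; i < N; ++i)
            for (int hh = 0; hh < 2; ++hh)
                for (int c = 0; c < C; ++c) {
                    const Hap &H = pop[c][2 * i + hh];
                    double prev = 0.0;
                    for (size_t k = 0; k < H.ends.size(); ++k, ++r) {
                        ind[r] = i + 1; hap[r] = hh + 1; chrom[r] = c + 1;
                        start[r] = prev; end[r] = H.ends[k]; anc[r] = H.anc[k];
                        prev = H.ends[k];
                    }
                }
        out["tracts"] = DataFrame::create(
            _["individual"] = ind, _["haplotype"] = hap, _["chrom"] = chrom,
            _["start_cM"] = start, _["end_cM"] = end, _["ancestry"] = anc);
    }
    return out;
}
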