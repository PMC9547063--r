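// Core numerics: empirical blood rheology laws, the repeated Poiseuille
// pressure solves and the discrete RBC tracking loop.
//
// Units used throughout: lengths/diameters um, pressure mmHg, flow um^3/ms,
// time ms, plasma viscosity Pa*s.  The unit-conversion constant PCONV turns
// pi*D^4/(128*L*mu) [um^3/(Pa*s) per um] into um^3/(ms*mmHg).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double PCONV = 0.133322; // (um^3/ms) per mmHg, see above

// ---------------------------------------------------------------------------
// Per-entity random streams (common random numbers): every boundary vessel
// owns its injection stream and every node its routing stream, all derived
// from the simulation seed.  Paired scenario comparisons (baseline vs
// dilated, same seed) then share injection times and routing draws, which
// removes a large part of the Monte-Carlo noise from their differences.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

struct Rng {
    uint64_t s = 0x853C49E6748FEA9BULL;
    void seed(uint64_t seq) {
        s = splitmix64(seq);
        if (s == 0) s = 0x9E3779B97F4A7C15ULL;
    }
    double unif() { // xorshift64*
        s ^= s >> 12;
        s ^= s << 25;
        s ^= s >> 27;
        uint64_t r = s * 2685821657736338717ULL;
        return (double)(r >> 11) * (1.0 / 9007199254740992.0);
    }
    int pois(double lambda) { // Knuth, fine for the small rates used here
        if (lambda <= 0.0) return 0;
        double Lc = std::exp(-lambda), p = 1.0;
        int k = 0;
        do { ++k; p *= unif(); } while (p > Lc);
        return k - 1;
    }
};

// ---------------------------------------------------------------------------
// Empirical in vitro rheology laws (Pries et al. parameterisation)
// ---------------------------------------------------------------------------

static inline double mu45f(double D) {
    return 220.0 * std::exp(-1.3 * D) + 3.2 -
           2.44 * std::exp(-0.06 * std::pow(D, 0.645));
}

static inline double shapeCf(double D) {
    double t = 1.0 / (1.0 + 1e-11 * std::pow(D, 12.0));
    return (0.8 + std::exp(-0.075 * D)) * (-1.0 + t) + t;
}

// relative effective viscosity, in vitro law; Hd is discharge hematocrit
static inline double murelf(double D, double Hd) {
    if (Hd <= 0.0) return 1.0;
    if (Hd > 0.99) Hd = 0.99;
    double C = shapeCf(D);
    double m45 = mu45f(D);
    double num = std::pow(1.0 - Hd, C) - 1.0;
    double den = std::pow(0.55, C) - 1.0;
    return 1.0 + (m45 - 1.0) * num / den;
}

// Fahraeus relation: HT/HD = HD + (1-HD)*X(D)
static inline double fahraeusX(double D) {
    return 1.0 + 1.7 * std::exp(-0.415 * D) - 0.6 * std::exp(-0.011 * D);
}

static inline double ht_from_hd(double Hd, double D) {
    if (Hd <= 0.0) return 0.0;
    if (Hd >= 1.0) return 1.0;
    double X = fahraeusX(D);
    double Ht = Hd * (Hd + (1.0 - Hd) * X);
    if (Ht > Hd) Ht = Hd; // RBCs are never slower than bulk
    return Ht;
}

// inverse of the Fahraeus relation (tube -> discharge), clamped so that
// discharge >= tube hematocrit
static inline double hd_from_ht(double Ht, double D) {
    if (Ht <= 0.0) return 0.0;
    if (Ht >= 1.0) return 1.0;
    double X = fahraeusX(D);
    double a = 1.0 - X;
    double Hd;
    if (std::fabs(a) < 1e-12) {
        Hd = Ht / X;
    } else {
        double disc = X * X + 4.0 * a * Ht;
        if (disc < 0.0) disc = 0.0;
        Hd = (-X + std::sqrt(disc)) / (2.0 * a);
    }
    if (Hd < Ht) Hd = Ht;
    if (Hd > 1.0) Hd = 1.0;
    return Hd;
}

static inline double logitf(double x) { return std::log(x / (1.0 - x)); }

// fraction of the parent RBC flux entering daughter "a", given the fraction
// of bulk flow into "a" (fqb), parent diameter Df, daughter diameters Da/Db
// and the parent discharge hematocrit.
static double phase_sep_frac(double fqb, double Df, double Da, double Db,
                             double Hd) {
    double x0 = 0.964 * (1.0 - Hd) / Df;
    if (x0 >= 0.5) return fqb > 0.5 ? 1.0 : (fqb < 0.5 ? 0.0 : 0.5);
    if (fqb <= x0) return 0.0;
    if (fqb >= 1.0 - x0) return 1.0;
    double r2 = (Da * Da) / (Db * Db);
    double A = -13.29 * ((r2 - 1.0) / (r2 + 1.0)) * (1.0 - Hd) / Df;
    double B = 1.0 + 6.98 * (1.0 - Hd) / Df;
    double z = A + B * logitf((fqb - x0) / (1.0 - 2.0 * x0));
    return 1.0 / (1.0 + std::exp(-z));
}

// [[Rcpp::export]]
NumericVector cpp_murel(NumericVector D, NumericVector Hd) {
    R_xlen_t n = std::max(D.size(), Hd.size());
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = murelf(D[i % D.size()], Hd[i % Hd.size()]);
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_hd_from_ht(NumericVector Ht, NumericVector D) {
    R_xlen_t n = std::max(Ht.size(), D.size());
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = hd_from_ht(Ht[i % Ht.size()], D[i % D.size()]);
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_ht_from_hd(NumericVector Hd, NumericVector D) {
    R_xlen_t n = std::max(Hd.size(), D.size());
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = ht_from_hd(Hd[i % Hd.size()], D[i % D.size()]);
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_phase_sep(NumericVector fqb, NumericVector Df,
                            NumericVector Da, NumericVector Db,
                            NumericVector Hd) {
    R_xlen_t n = fqb.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = phase_sep_frac(fqb[i], Df[i % Df.size()], Da[i % Da.size()],
                                Db[i % Db.size()], Hd[i % Hd.size()]);
    return out;
}

// ---------------------------------------------------------------------------
// Network + simulation state
// ---------------------------------------------------------------------------

struct Net {
    int nN, nE;
    std::vector<int> ea, eb;            // 0-based endpoints
    std::vector<double> D, L, area, vol, g0;
    std::vector<char> isb;              // boundary flag per node
    std::vector<double> pbc;            // boundary pressure (NA if none)
    std::vector<std::vector<int>> inc;  // node -> incident edges
    double singleFileMax;
    double htCap = 1.0, rbcVolume = 55.0; // occlusion rule parameters
};

static Net buildNet(const IntegerVector& ea, const IntegerVector& eb,
                    const NumericVector& D, const NumericVector& L,
                    const LogicalVector& isb, const NumericVector& pbc,
                    double plasmaVisc, double singleFileMax) {
    Net net;
    net.nE = ea.size();
    net.nN = isb.size();
    net.singleFileMax = singleFileMax;
    net.ea.assign(ea.begin(), ea.end());
    net.eb.assign(eb.begin(), eb.end());
    net.D.assign(D.begin(), D.end());
    net.L.assign(L.begin(), L.end());
    net.isb.resize(net.nN);
    net.pbc.assign(pbc.begin(), pbc.end());
    for (int i = 0; i < net.nN; ++i) net.isb[i] = isb[i] ? 1 : 0;
    net.area.resize(net.nE);
    net.vol.resize(net.nE);
    net.g0.resize(net.nE);
    const double pi = M_PI;
    for (int e = 0; e < net.nE; ++e) {
        net.area[e] = pi * net.D[e] * net.D[e] / 4.0;
        net.vol[e] = net.area[e] * net.L[e];
        net.g0[e] = PCONV * pi * std::pow(net.D[e], 4.0) /
                    (128.0 * net.L[e] * plasmaVisc);
    }
    net.inc.assign(net.nN, {});
    for (int e = 0; e < net.nE; ++e) {
        net.inc[net.ea[e]].push_back(e);
        net.inc[net.eb[e]].push_back(e);
    }
    return net;
}

static inline int otherNode(const Net& net, int e, int n) {
    return net.ea[e] == n ? net.eb[e] : net.ea[e];
}

// flow in edge e directed away from node n?
static inline bool flowsAway(const Net& net, const std::vector<double>& q,
                             int e, int n) {
    if (std::fabs(q[e]) <= 1e-14) return false;
    return (net.ea[e] == n) ? (q[e] > 0.0) : (q[e] < 0.0);
}

// ---------------------------------------------------------------------------
// Sparse SPD solver: interior-node Laplacian, IC(0)-preconditioned CG
// ---------------------------------------------------------------------------

struct Solver {
    int m;                              // number of interior nodes
    std::vector<int> nodeOf;            // interior idx -> node
    std::vector<int> intIdx;            // node -> interior idx (-1 if bc)
    // full CSR pattern
    std::vector<int> rp, ci, diagPos;
    std::vector<double> av;
    // per-edge assembly positions: -1 if absent
    std::vector<int> posAB, posBA;
    // lower-triangular pattern for IC(0)
    std::vector<int> lrp, lci;
    std::vector<double> lval, ldiag, adiaglow;
    // CSC access to lower factor for backward solve
    std::vector<int> crp, cri, cpos;
    std::vector<double> b, r, z, d, Ad;

    void init(const Net& net) {
        intIdx.assign(net.nN, -1);
        for (int n = 0; n < net.nN; ++n)
            if (!net.isb[n]) { intIdx[n] = (int)nodeOf.size(); nodeOf.push_back(n); }
        m = (int)nodeOf.size();
        // pattern: diagonal + interior neighbors (unique)
        std::vector<std::vector<int>> cols(m);
        for (int k = 0; k < m; ++k) cols[k].push_back(k);
        for (int e = 0; e < net.nE; ++e) {
            int ia = intIdx[net.ea[e]], ib = intIdx[net.eb[e]];
            if (ia >= 0 && ib >= 0) {
                cols[ia].push_back(ib);
                cols[ib].push_back(ia);
            }
        }
        rp.assign(m + 1, 0);
        for (int k = 0; k < m; ++k) {
            std::sort(cols[k].begin(), cols[k].end());
            cols[k].erase(std::unique(cols[k].begin(), cols[k].end()),
                          cols[k].end());
            rp[k + 1] = rp[k] + (int)cols[k].size();
        }
        ci.resize(rp[m]);
        diagPos.resize(m);
        for (int k = 0; k < m; ++k)
            for (size_t j = 0; j < cols[k].size(); ++j) {
                ci[rp[k] + j] = cols[k][j];
                if (cols[k][j] == k) diagPos[k] = rp[k] + (int)j;
            }
        av.assign(rp[m], 0.0);
        // edge -> positions
        posAB.assign(net.nE, -1);
        posBA.assign(net.nE, -1);
        for (int e = 0; e < net.nE; ++e) {
            int ia = intIdx[net.ea[e]], ib = intIdx[net.eb[e]];
            if (ia >= 0 && ib >= 0) {
                posAB[e] = findPos(ia, ib);
                posBA[e] = findPos(ib, ia);
            }
        }
        // lower pattern
        lrp.assign(m + 1, 0);
        for (int k = 0; k < m; ++k) {
            int c = 0;
            for (int j = rp[k]; j < rp[k + 1]; ++j) if (ci[j] < k) ++c;
            lrp[k + 1] = lrp[k] + c;
        }
        lci.resize(lrp[m]);
        for (int k = 0, idx = 0; k < m; ++k)
            for (int j = rp[k]; j < rp[k + 1]; ++j)
                if (ci[j] < k) lci[idx++] = ci[j];
        lval.assign(lrp[m], 0.0);
        ldiag.assign(m, 0.0);
        adiaglow.assign(m, 0.0);
        // CSC of lower pattern
        crp.assign(m + 1, 0);
        for (int idx = 0; idx < lrp[m]; ++idx) crp[lci[idx] + 1]++;
        for (int k = 0; k < m; ++k) crp[k + 1] += crp[k];
        cri.resize(lrp[m]);
        cpos.resize(lrp[m]);
        std::vector<int> fill(crp.begin(), crp.end() - 1);
        for (int k = 0; k < m; ++k)
            for (int idx = lrp[k]; idx < lrp[k + 1]; ++idx) {
                int j = lci[idx];
                cri[fill[j]] = k;
                cpos[fill[j]] = idx;
                fill[j]++;
            }
        b.assign(m, 0.0);
        r.assign(m, 0.0);
        z.assign(m, 0.0);
        d.assign(m, 0.0);
        Ad.assign(m, 0.0);
    }

    int findPos(int row, int col) const {
        int lo = rp[row], hi = rp[row + 1];
        const int* first = ci.data() + lo;
        const int* it = std::lower_bound(first, ci.data() + hi, col);
        return lo + (int)(it - first);
    }

    void assemble(const Net& net, const std::vector<double>& g) {
        std::fill(av.begin(), av.end(), 0.0);
        std::fill(b.begin(), b.end(), 0.0);
        for (int e = 0; e < net.nE; ++e) {
            int na = net.ea[e], nb = net.eb[e];
            int ia = intIdx[na], ib = intIdx[nb];
            if (ia >= 0) av[diagPos[ia]] += g[e];
            if (ib >= 0) av[diagPos[ib]] += g[e];
            if (ia >= 0 && ib >= 0) {
                av[posAB[e]] -= g[e];
                av[posBA[e]] -= g[e];
            } else if (ia >= 0) {
                b[ia] += g[e] * net.pbc[nb];
            } else if (ib >= 0) {
                b[ib] += g[e] * net.pbc[na];
            }
        }
    }

    void factorIC0() {
        // copy lower values from A
        for (int k = 0, idx = 0; k < m; ++k) {
            adiaglow[k] = av[diagPos[k]];
            for (int j = rp[k]; j < rp[k + 1]; ++j)
                if (ci[j] < k) lval[idx++] = av[j];
        }
        for (int i = 0; i < m; ++i) {
            for (int idx = lrp[i]; idx < lrp[i + 1]; ++idx) {
                int j = lci[idx];
                double s = lval[idx];
                // subtract dot of rows i and j over cols < j
                int pi_ = lrp[i], pj = lrp[j];
                while (pi_ < idx && pj < lrp[j + 1]) {
                    if (lci[pi_] == lci[pj]) s -= lval[pi_++] * lval[pj++];
                    else if (lci[pi_] < lci[pj]) ++pi_;
                    else ++pj;
                }
                lval[idx] = s / ldiag[j];
            }
            double dsum = adiaglow[i];
            for (int idx = lrp[i]; idx < lrp[i + 1]; ++idx)
                dsum -= lval[idx] * lval[idx];
            if (dsum < 1e-300) dsum = 1e-300;
            ldiag[i] = std::sqrt(dsum);
        }
    }

    void matvec(const std::vector<double>& x, std::vector<double>& out) const {
        for (int k = 0; k < m; ++k) {
            double s = 0.0;
            for (int j = rp[k]; j < rp[k + 1]; ++j) s += av[j] * x[ci[j]];
            out[k] = s;
        }
    }

    void precSolve(const std::vector<double>& rhs, std::vector<double>& out) {
        // forward: L y = rhs (store y in out)
        for (int i = 0; i < m; ++i) {
            double s = rhs[i];
            for (int idx = lrp[i]; idx < lrp[i + 1]; ++idx)
                s -= lval[idx] * out[lci[idx]];
            out[i] = s / ldiag[i];
        }
        // backward: L^T z = y
        for (int i = m - 1; i >= 0; --i) {
            double s = out[i];
            for (int idx = crp[i]; idx < crp[i + 1]; ++idx)
                s -= lval[cpos[idx]] * out[cri[idx]];
            out[i] = s / ldiag[i];
        }
    }

    // true residual r = b - A x; returns inf norm
    double trueResidual(const std::vector<double>& x) {
        matvec(x, Ad);
        double rinf = 0.0;
        for (int k = 0; k < m; ++k) {
            r[k] = b[k] - Ad[k];
            rinf = std::max(rinf, std::fabs(r[k]));
        }
        return rinf;
    }

    // solve A x = b with warm start x; absolute inf-norm tolerance.
    // Convergence is always confirmed against the true residual (the
    // recursive CG residual drifts); on failed confirmation CG restarts.
    // Returns iterations used.
    int pcg(std::vector<double>& x, double tolAbs, int maxit) {
        double rinf = trueResidual(x);
        if (rinf <= tolAbs) return 0;
        double best = rinf;
        int noProgress = 0;
        precSolve(r, z);
        d = z;
        double rz = 0.0;
        for (int k = 0; k < m; ++k) rz += r[k] * z[k];
        int it = 0;
        while (it < maxit) {
            ++it;
            matvec(d, Ad);
            double dAd = 0.0;
            for (int k = 0; k < m; ++k) dAd += d[k] * Ad[k];
            if (dAd <= 0.0) break;
            double alpha = rz / dAd;
            rinf = 0.0;
            for (int k = 0; k < m; ++k) {
                x[k] += alpha * d[k];
                r[k] -= alpha * Ad[k];
                rinf = std::max(rinf, std::fabs(r[k]));
            }
            bool restart = false;
            if (rinf <= tolAbs || it % 128 == 0) {
                rinf = trueResidual(x);     // confirm / refresh
                if (rinf <= tolAbs) break;
                if (rinf < 0.9 * best) { best = rinf; noProgress = 0; }
                else if (++noProgress >= 4) break; // numerical floor
                restart = true;
            }
            precSolve(r, z);
            double rznew = 0.0;
            for (int k = 0; k < m; ++k) rznew += r[k] * z[k];
            double beta = restart ? 0.0 : rznew / rz;
            rz = rznew;
            for (int k = 0; k < m; ++k) d[k] = z[k] + beta * d[k];
        }
        return it;
    }
};

// ---------------------------------------------------------------------------
// RBC state and stepping
// ---------------------------------------------------------------------------

struct SimState {
    std::vector<double> p, q, g, ht, hd, vr; // per node / per edge
    std::vector<int> cnt;                    // RBC count per edge
    std::vector<int> rv;                     // RBC -> edge
    std::vector<double> rx;                  // RBC arc position (from node a)
    std::vector<char> atnode;                // clamped at a node end?
    long injected = 0, exited = 0;
    std::vector<double> departures;          // per edge (window only)
    std::vector<Rng> injRng;                 // per edge
    std::vector<Rng> routeRng;               // per node
};

// update tube/discharge hematocrit, viscosity-scaled conductance
static void updateHema(const Net& net, SimState& st, double rbcVolume,
                       double htCap, long* jam) {
    for (int e = 0; e < net.nE; ++e) {
        double h = st.cnt[e] * rbcVolume / net.vol[e];
        if (h > htCap) { h = htCap; if (jam) (*jam)++; }
        st.ht[e] = h;
        st.hd[e] = hd_from_ht(h, net.D[e]);
        st.g[e] = net.g0[e] / murelf(net.D[e], st.hd[e]);
    }
}

static void updateFlowsVel(const Net& net, SimState& st) {
    for (int e = 0; e < net.nE; ++e) {
        st.q[e] = st.g[e] * (st.p[net.ea[e]] - st.p[net.eb[e]]);
        double u = st.q[e] / net.area[e];
        double ratio = st.ht[e] > 0.0 ? st.hd[e] / st.ht[e]
                                      : 1.0 / fahraeusX(net.D[e]);
        st.vr[e] = u * ratio;
    }
}

// route one RBC sitting at node n coming from edge e; returns:
//  -1 exit domain, -2 stay put, otherwise new edge index
static int routeRbc(const Net& net, SimState& st, int n, int e) {
    if (net.isb[n]) return -1;
    // collect outflow edges
    int out[8];
    int nout = 0;
    for (int f : net.inc[n]) {
        if (flowsAway(net, st.q, f, n)) {
            if (nout < 8) out[nout++] = f;
        }
    }
    if (nout == 0) return -2;
    // occlusion: a vessel already at the hematocrit cap accepts no cell;
    // full daughters are excluded from the choice (the cell waits only
    // when every outflow is full)
    auto full = [&](int f) {
        return (st.cnt[f] + 1) * net.rbcVolume / net.vol[f] > net.htCap;
    };
    {
        int nk = 0;
        for (int k = 0; k < nout; ++k)
            if (!full(out[k])) out[nk++] = out[k];
        if (nk == 0) return -2;
        nout = nk;
    }
    if (nout == 1) return out[0];
    if (net.D[e] > net.singleFileMax) {
        // empirical phase separation; >2 outflows reduced to sequential
        // binary splits ordered by flow (area-equivalent rest diameter)
        std::sort(out, out + nout, [&](int a, int b) {
            return std::fabs(st.q[a]) > std::fabs(st.q[b]);
        });
        double hd = st.hd[e];
        int lo = 0;
        while (lo < nout - 1) {
            double qa = std::fabs(st.q[out[lo]]);
            double qrest = 0.0, d2 = 0.0;
            for (int k = lo + 1; k < nout; ++k) {
                qrest += std::fabs(st.q[out[k]]);
                d2 += net.D[out[k]] * net.D[out[k]];
            }
            double fr = phase_sep_frac(qa / (qa + qrest), net.D[e],
                                       net.D[out[lo]], std::sqrt(d2), hd);
            if (st.routeRng[n].unif() < fr) return out[lo];
            ++lo;
        }
        return out[nout - 1];
    }
    // single-file: the cell follows the path of the largest pressure
    // force.  At the junction mouth the force dragging the cell into a
    // branch is the viscous drag of that branch's stream, proportional
    // to its bulk flow; routing into the strongest stream is also
    // self-limiting (a loaded branch slows down and stops collecting).
    double best = -1.0;
    int nbest = 0;
    int bests[8];
    for (int k = 0; k < nout; ++k) {
        int f = out[k];
        double force = std::fabs(st.q[f]);
        if (force > best * (1.0 + 1e-12)) {
            best = force;
            nbest = 0;
            bests[nbest++] = f;
        } else if (force >= best * (1.0 - 1e-12)) {
            if (nbest < 8) bests[nbest++] = f;
        }
    }
    return (nbest == 1) ? bests[0]
                        : bests[(int)(st.routeRng[n].unif() * nbest) % nbest];
}

// route all clamped RBCs, then advance all RBCs by dt
static void stepRbcs(const Net& net, SimState& st, double dt, bool countDep) {
    // routing pass; cells that could not be routed park (atnode = 2)
    // until the next pressure re-solve changes flows or frees space
    for (size_t i = 0; i < st.rv.size();) {
        if (st.atnode[i] != 1) { ++i; continue; }
        int e = st.rv[i];
        int n = (st.rx[i] <= 0.0) ? net.ea[e] : net.eb[e];
        int res = routeRbc(net, st, n, e);
        if (res == -2) { st.atnode[i] = 2; ++i; continue; }
        st.cnt[e]--;
        if (countDep) st.departures[e] += 1.0;
        if (res == -1) {
            st.exited++;
            st.rv[i] = st.rv.back(); st.rv.pop_back();
            st.rx[i] = st.rx.back(); st.rx.pop_back();
            st.atnode[i] = st.atnode.back(); st.atnode.pop_back();
            continue; // do not advance i
        }
        st.cnt[res]++;
        st.rv[i] = res;
        st.rx[i] = (net.ea[res] == n) ? 0.0 : net.L[res];
        st.atnode[i] = 0;
        ++i;
    }
    // advance pass
    for (size_t i = 0; i < st.rv.size(); ++i) {
        if (st.atnode[i]) continue;
        int e = st.rv[i];
        double x = st.rx[i] + st.vr[e] * dt;
        if (x >= net.L[e]) { x = net.L[e]; st.atnode[i] = 1; }
        else if (x <= 0.0) { x = 0.0; st.atnode[i] = 1; }
        st.rx[i] = x;
    }
}

// Poisson injection at inflow boundary vessel ends
static void inject(const Net& net, SimState& st, double inflowH,
                   double rbcVolume, double dt) {
    for (int e = 0; e < net.nE; ++e) {
        if (std::fabs(st.q[e]) <= 1e-14) continue;
        int up = st.q[e] > 0.0 ? net.ea[e] : net.eb[e];
        if (!net.isb[up]) continue;
        if ((st.cnt[e] + 1) * net.rbcVolume / net.vol[e] > net.htCap)
            continue; // entry vessel full
        double lam = std::fabs(st.q[e]) * inflowH / rbcVolume * dt;
        int nnew = st.injRng[e].pois(lam);
        for (int k = 0; k < nnew; ++k) {
            st.rv.push_back(e);
            st.rx.push_back(net.ea[e] == up ? 0.0 : net.L[e]);
            st.atnode.push_back(0);
            st.cnt[e]++;
            st.injected++;
        }
    }
}

// [[Rcpp::export]]
List cpp_simulate(IntegerVector ea, IntegerVector eb, NumericVector D,
                  NumericVector L, LogicalVector isBoundary,
                  NumericVector pBoundary, double plasmaVisc,
                  double singleFileMax, double inflowHematocrit, double dt,
                  int warmupSteps, int windowSteps, int couplingInterval,
                  double rbcVolume, double htCap, bool seedInitial,
                  int seed) {
    Net net = buildNet(ea, eb, D, L, isBoundary, pBoundary, plasmaVisc,
                       singleFileMax);
    net.htCap = htCap;
    net.rbcVolume = rbcVolume;
    Solver sol;
    sol.init(net);

    // solve in pressures relative to the mean boundary pressure: pressure
    // differences (all that matters physically) lose less precision
    double pshift = 0.0;
    {
        int nb = 0;
        for (int n = 0; n < net.nN; ++n)
            if (net.isb[n]) { pshift += net.pbc[n]; ++nb; }
        if (nb == 0) stop("no boundary pressure nodes");
        pshift /= nb;
        for (int n = 0; n < net.nN; ++n)
            if (net.isb[n]) net.pbc[n] -= pshift;
    }

    SimState st;
    st.p.assign(net.nN, 0.0);
    st.q.assign(net.nE, 0.0);
    st.g.assign(net.nE, 0.0);
    st.ht.assign(net.nE, 0.0);
    st.hd.assign(net.nE, 0.0);
    st.vr.assign(net.nE, 0.0);
    st.cnt.assign(net.nE, 0);
    st.departures.assign(net.nE, 0.0);
    st.injRng.resize(net.nE);
    st.routeRng.resize(net.nN);
    for (int e = 0; e < net.nE; ++e)
        st.injRng[e].seed(((uint64_t)(uint32_t)seed << 32) ^ (uint64_t)e);
    for (int n = 0; n < net.nN; ++n)
        st.routeRng[n].seed(((uint64_t)(uint32_t)seed << 32) ^
                            (0x80000000ULL + (uint64_t)n));

    // boundary pressures fixed in p (shifted frame); interior starts at 0
    for (int n = 0; n < net.nN; ++n)
        st.p[n] = net.isb[n] ? net.pbc[n] : 0.0;

    // initial RBC seeding at the inflow hematocrit (tube equivalent)
    long initialCount = 0;
    if (seedInitial && inflowHematocrit > 0.0) {
        for (int e = 0; e < net.nE; ++e) {
            double target = ht_from_hd(inflowHematocrit, net.D[e]);
            double expct = target * net.vol[e] / rbcVolume;
            int n0 = (int)std::floor(expct);
            if (st.injRng[e].unif() < expct - n0) n0++;
            for (int k = 0; k < n0; ++k) {
                st.rv.push_back(e);
                st.rx.push_back(st.injRng[e].unif() * net.L[e]);
                st.atnode.push_back(0);
                st.cnt[e]++;
            }
        }
        initialCount = (long)st.rv.size();
    }

    int totalSteps = warmupSteps + windowSteps;
    long jam = 0;
    double maxImb = 0.0;       // max over resolves of max|sum q| / mean|q|
    double meanAbsQ = 1.0;
    bool first = true;
    std::vector<double> sumq(net.nE, 0.0), sumhd(net.nE, 0.0);
    std::vector<double> qmin(net.nE, R_PosInf), qmax(net.nE, R_NegInf);
    int segStart = 0;
    long totalCgIter = 0;

    auto flushSegment = [&](int from, int to) {
        int lo = std::max(from, warmupSteps);
        int hi = std::min(to, totalSteps);
        int nseg = hi - lo;
        if (nseg <= 0) return;
        for (int e = 0; e < net.nE; ++e) {
            sumq[e] += st.q[e] * nseg;
            sumhd[e] += st.hd[e] * nseg;
            if (st.q[e] < qmin[e]) qmin[e] = st.q[e];
            if (st.q[e] > qmax[e]) qmax[e] = st.q[e];
        }
    };

    std::vector<double> x(sol.m, 0.0);

    auto resolve = [&](int step) {
        flushSegment(segStart, step);
        segStart = step;
        updateHema(net, st, rbcVolume, htCap, &jam);
        sol.assemble(net, st.g);
        sol.factorIC0();
        double binf = 0.0;
        for (int k = 0; k < sol.m; ++k) binf = std::max(binf, std::fabs(sol.b[k]));
        double tol = first ? std::max(1e-13 * binf, 1e-300)
                           : std::max(1e-12 * meanAbsQ, 1e-300);
        totalCgIter += sol.pcg(x, tol, 5000);
        for (int k = 0; k < sol.m; ++k) st.p[sol.nodeOf[k]] = x[k];
        updateFlowsVel(net, st);
        double mq = 0.0;
        for (int e = 0; e < net.nE; ++e) mq += std::fabs(st.q[e]);
        mq = net.nE > 0 ? mq / net.nE : 0.0;
        if (first && mq > 0.0) { // tighten to flow-scaled tolerance
            totalCgIter += sol.pcg(x, std::max(1e-12 * mq, 1e-300), 5000);
            for (int k = 0; k < sol.m; ++k) st.p[sol.nodeOf[k]] = x[k];
            updateFlowsVel(net, st);
        }
        meanAbsQ = mq > 0.0 ? mq : meanAbsQ;
        // wake parked RBCs: flows and occupancy have changed
        for (size_t i = 0; i < st.atnode.size(); ++i)
            if (st.atnode[i] == 2) st.atnode[i] = 1;
        // conservation diagnostic at interior nodes
        double imb = 0.0;
        for (int k = 0; k < sol.m; ++k) {
            int n = sol.nodeOf[k];
            double s = 0.0;
            for (int f : net.inc[n])
                s += (net.ea[f] == n ? -st.q[f] : st.q[f]);
            imb = std::max(imb, std::fabs(s));
        }
        if (meanAbsQ > 0.0) maxImb = std::max(maxImb, imb / meanAbsQ);
        first = false;
    };

    resolve(0);
    // time-step sanity: an RBC must not jump a whole vessel per step
    double vmax = 0.0, lmin = R_PosInf;
    for (int e = 0; e < net.nE; ++e) {
        vmax = std::max(vmax, std::fabs(st.vr[e]));
        lmin = std::min(lmin, net.L[e]);
    }
    if (vmax * dt > lmin)
        stop("time step too large: an RBC would traverse a whole vessel in "
             "one step; choose time_step <= %g ms", lmin / vmax);

    for (int step = 0; step < totalSteps; ++step) {
        if (step > 0 && step % couplingInterval == 0) resolve(step);
        stepRbcs(net, st, dt, step >= warmupSteps);
        if (inflowHematocrit > 0.0)
            inject(net, st, inflowHematocrit, rbcVolume, dt);
    }
    flushSegment(segStart, totalSteps);

    double windowMs = windowSteps * dt;
    NumericVector meanFlow(net.nE), meanHd(net.nE), flux(net.nE);
    NumericVector flowMin(net.nE), flowMax(net.nE);
    for (int e = 0; e < net.nE; ++e) {
        meanFlow[e] = sumq[e] / windowSteps;
        meanHd[e] = sumhd[e] / windowSteps;
        flux[e] = st.departures[e] / (windowMs / 1000.0); // RBCs per second
        flowMin[e] = qmin[e];
        flowMax[e] = qmax[e];
    }
    NumericVector pr(net.nN), qq(net.nE), hht(net.nE), hhd(net.nE);
    IntegerVector ccnt(net.nE);
    for (int n = 0; n < net.nN; ++n) pr[n] = st.p[n] + pshift;
    for (int e = 0; e < net.nE; ++e) {
        qq[e] = st.q[e];
        hht[e] = st.ht[e];
        hhd[e] = st.hd[e];
        ccnt[e] = st.cnt[e];
    }
    return List::create(
        _["meanFlow"] = meanFlow, _["meanDischargeHematocrit"] = meanHd,
        _["rbcFlux"] = flux, _["flowMin"] = flowMin, _["flowMax"] = flowMax,
        _["pressures"] = pr, _["flows"] = qq, _["tubeHematocrit"] = hht,
        _["dischargeHematocrit"] = hhd, _["rbcCount"] = ccnt,
        _["rbcInitial"] = (double)initialCount,
        _["rbcInjected"] = (double)st.injected,
        _["rbcExited"] = (double)st.exited,
        _["rbcFinal"] = (double)st.rv.size(),
        _["maxRelImbalance"] = maxImb, _["jamEvents"] = (double)jam,
        _["cgIterations"] = (double)totalCgIter);
}

// Single coupled step on an explicit RBC state: route clamped RBCs, then
// advance by dt using the supplied pressure/flow field.  Shares the routing
// and advection code with the main loop.
// [[Rcpp::export]]
List cpp_advance_rbcs(IntegerVector ea, IntegerVector eb, NumericVector D,
                      NumericVector L, LogicalVector isBoundary,
                      NumericVector pressures, NumericVector flows,
                      NumericVector tubeHematocrit, IntegerVector rbcVessel,
                      NumericVector rbcPos, LogicalVector rbcAtNode,
                      double dt, double singleFileMax, int seed) {
    NumericVector pbc(isBoundary.size(), 0.0);
    Net net = buildNet(ea, eb, D, L, isBoundary, pbc, 1e-3, singleFileMax);
    SimState st;
    st.p.assign(pressures.begin(), pressures.end());
    st.q.assign(flows.begin(), flows.end());
    st.ht.assign(tubeHematocrit.begin(), tubeHematocrit.end());
    st.hd.resize(net.nE);
    st.vr.resize(net.nE);
    st.g.assign(net.nE, 0.0);
    st.cnt.assign(net.nE, 0);
    st.departures.assign(net.nE, 0.0);
    st.injRng.resize(net.nE);
    st.routeRng.resize(net.nN);
    for (int e = 0; e < net.nE; ++e)
        st.injRng[e].seed(((uint64_t)(uint32_t)seed << 32) ^ (uint64_t)e);
    for (int n = 0; n < net.nN; ++n)
        st.routeRng[n].seed(((uint64_t)(uint32_t)seed << 32) ^
                            (0x80000000ULL + (uint64_t)n));
    for (int e = 0; e < net.nE; ++e) {
        st.hd[e] = hd_from_ht(st.ht[e], net.D[e]);
        double u = st.q[e] / net.area[e];
        double ratio = st.ht[e] > 0.0 ? st.hd[e] / st.ht[e]
                                      : 1.0 / fahraeusX(net.D[e]);
        st.vr[e] = u * ratio;
    }
    int nr = rbcVessel.size();
    for (int i = 0; i < nr; ++i) {
        st.rv.push_back(rbcVessel[i] - 1);
        st.rx.push_back(rbcPos[i]);
        st.atnode.push_back(rbcAtNode[i] ? 1 : 0);
        st.cnt[rbcVessel[i] - 1]++;
    }
    stepRbcs(net, st, dt, true);
    int nout = (int)st.rv.size();
    IntegerVector ov(nout);
    NumericVector op(nout);
    LogicalVector oa(nout);
    for (int i = 0; i < nout; ++i) {
        ov[i] = st.rv[i] + 1;
        op[i] = st.rx[i];
        oa[i] = st.atnode[i] != 0;
    }
    NumericVector dep(net.nE);
    for (int e = 0; e < net.nE; ++e) dep[e] = st.departures[e];
    return List::create(_["vessel"] = ov, _["position"] = op,
                        _["atNode"] = oa, _["exited"] = (double)st.exited,
                        _["departures"] = dep);
}
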