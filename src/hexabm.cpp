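#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Periodic hexagonal lattice in axial (rhombic) coordinates. The six
// nearest neighbours of (i, j) are offsets
// {(1,0), (-1,0), (0,1), (0,-1), (1,-1), (-1,1)}, giving every site a
// uniform degree of 6 with no edge effects.
static const int DI[6] = { 1, -1, 0,  0, 1, -1 };
static const int DJ[6] = { 0,  0, 1, -1, -1, 1 };

struct HexLattice {
    int rows, cols, N;
    std::vector<int> occ;     // 0/1 occupancy
    std::vector<int> ncnt;    // occupied-neighbour count, every site
    std::vector<int> cls;     // class (= ncnt) of occupied sites, -1 if empty
    std::vector<int> pos;     // index within class member list
    std::vector<int> members[7];
    int nocc;

    int idx(int i, int j) const { return i * cols + j; }

    int neighbour(int s, int k) const {
        int i = s / cols, j = s % cols;
        int ni = i + DI[k], nj = j + DJ[k];
        if (ni < 0) ni += rows; else if (ni >= rows) ni -= rows;
        if (nj < 0) nj += cols; else if (nj >= cols) nj -= cols;
        return ni * cols + nj;
    }

    void init(const IntegerMatrix& occ0) {
        rows = occ0.nrow(); cols = occ0.ncol(); N = rows * cols;
        occ.assign(N, 0); ncnt.assign(N, 0);
        cls.assign(N, -1); pos.assign(N, -1);
        nocc = 0;
        for (int i = 0; i < rows; ++i)
            for (int j = 0; j < cols; ++j)
                occ[idx(i, j)] = occ0(i, j) ? 1 : 0;
        for (int s = 0; s < N; ++s) {
            int c = 0;
            for (int k = 0; k < 6; ++k) c += occ[neighbour(s, k)];
            ncnt[s] = c;
        }
        for (int s = 0; s < N; ++s)
            if (occ[s]) { enlist(s); ++nocc; }
    }

    void enlist(int s) {
        int n = ncnt[s];
        cls[s] = n;
        pos[s] = (int)members[n].size();
        members[n].push_back(s);
    }

    void delist(int s) {
        int n = cls[s], p = pos[s];
        int last = members[n].back();
        members[n][p] = last;
        pos[last] = p;
        members[n].pop_back();
        cls[s] = -1; pos[s] = -1;
    }

    void reclass(int s) {
        if (cls[s] == ncnt[s]) return;
        delist(s);
        enlist(s);
    }

    void add_site(int s) {
        occ[s] = 1;
        enlist(s);
        ++nocc;
        for (int k = 0; k < 6; ++k) {
            int t = neighbour(s, k);
            ++ncnt[t];
            if (occ[t]) reclass(t);
        }
    }

    void remove_site(int s) {
        delist(s);
        occ[s] = 0;
        --nocc;
        for (int k = 0; k < 6; ++k) {
            int t = neighbour(s, k);
            --ncnt[t];
            if (occ[t]) reclass(t);
        }
    }
};

// Exact (Gillespie) simulation of the exclusion process: each occupied
// site with n occupied neighbours dies at rate d[n], attempts
// proliferation at rate p[n] (a uniformly chosen neighbour site receives
// the daughter unless occupied), and attempts a move at rate m (likewise
// aborted if the target is occupied). n is evaluated at event execution
// time. Returns the lattice density at record_times (state immediately
// before any event at the same instant). Uses R's RNG.
// [[Rcpp::export]]
NumericVector hex_gillespie(IntegerMatrix occ0, NumericVector p,
                            NumericVector d, double m,
                            NumericVector record_times) {
    if (p.size() != 6 || d.size() != 7)
        stop("'p' must have length 6 and 'd' length 7");
    HexLattice L;
    L.init(occ0);

    // attempt rate per class; sites with all 6 neighbours occupied can
    // never place a daughter, so their (always aborted) proliferation
    // attempts are dropped from the event menu
    double rate[7];
    for (int n = 0; n < 7; ++n)
        rate[n] = (n < 6 ? p[n] : 0.0) + d[n] + m;

    const int nrec = record_times.size();
    NumericVector out(nrec);
    double t = 0.0;
    int rec = 0;
    while (rec < nrec && record_times[rec] <= t) {
        out[rec] = (double)L.nocc / L.N;
        ++rec;
    }
    const double tmax = nrec ? record_times[nrec - 1] : 0.0;

    while (rec < nrec) {
        double total = 0.0;
        for (int n = 0; n < 7; ++n)
            total += rate[n] * L.members[n].size();
        if (total <= 0.0) break;  // frozen (e.g. extinct): density constant

        double dt = R::exp_rand() / total;
        double tnew = t + dt;
        while (rec < nrec && record_times[rec] <= tnew) {
            out[rec] = (double)L.nocc / L.N;
            ++rec;
        }
        t = tnew;
        if (t > tmax) break;

        // select class, then site uniformly within the class
        double u = R::unif_rand() * total;
        int n = 0;
        for (; n < 6; ++n) {
            double w = rate[n] * L.members[n].size();
            if (u < w) break;
            u -= w;
        }
        if (L.members[n].empty()) continue;  // guard against roundoff
        int s = L.members[n][(int)(R::unif_rand() * L.members[n].size())];
        n = L.ncnt[s];

        double v = R::unif_rand() * rate[n];
        if (v < d[n]) {
            L.remove_site(s);
        } else if (n < 6 && v < d[n] + p[n]) {
            int target = L.neighbour(s, (int)(R::unif_rand() * 6));
            if (!L.occ[target]) L.add_site(target);
        } else if (v >= rate[n] - m) {
            int target = L.neighbour(s, (int)(R::unif_rand() * 6));
            if (!L.occ[target]) {
                L.remove_site(s);
                L.add_site(target);
            }
        }
    }
    // frozen state persists to the end of the recording grid
    while (rec < nrec) { out[rec] = (double)L.nocc / L.N; ++rec; }
    return out;
}

// Occupied-neighbour counts for every site of a periodic axial hexagonal
// lattice (testing aid; the simulator maintains these incrementally).
// [[Rcpp::export]]
IntegerMatrix hex_neighbour_counts(IntegerMatrix occ0) {
    HexLattice L;
    L.init(occ0);
    IntegerMatrix out(L.rows, L.cols);
    for (int i = 0; i < L.rows; ++i)
        for (int j = 0; j < L.cols; ++j)
            out(i, j) = L.ncnt[L.idx(i, j)];
    return out;
}
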