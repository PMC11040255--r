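// Exact Gillespie simulation of the predator-prey-parasite reaction network.
//
// State order everywhere: (xU, xI, yU, yI, z)
// Parameter order:        (gx, rx, dx, K, S, Qx, nz, dz, fy, ky, Qy, rp, re, dy)
//
// The 24 effective channels (null reactions dropped, outcome probabilities
// folded into the rates) must stay in lock-step with the R-level network in
// R/model.R; a unit test compares both channel-by-channel.

#include <Rcpp.h>
using namespace Rcpp;

static const int NCH = 24;
static const int NSP = 5;

// propensities a[] at state s under parameters P
static void fill_propensities(const double *s, const double *P, double *a) {
    const double gx = P[0], rx = P[1], dx = P[2], K = P[3], S = P[4],
                 Qx = P[5], dz = P[7], fy = P[8], ky = P[9],
                 Qy = P[10], rp = P[11], re = P[12], dy = P[13];
    const double xU = s[0], xI = s[1], yU = s[2], yI = s[3], z = s[4];

    a[0]  = gx * rx * xI;                              // XI -> XI + XU
    a[1]  = gx * xU;                                   // XU -> XU + XU
    a[2]  = xI * (xI - 1.0) / K;                       // XI + XI -> XI
    a[3]  = xI * xU / K;                               // XI + XU -> XI
    a[4]  = xU * xI / K;                               // XU + XI -> XU
    a[5]  = xU * (xU - 1.0) / K;                       // XU + XU -> XU
    a[6]  = Qx * S * xU * z;                           // XU + Z -> XI
    a[7]  = ky * fy * xU * yU;                         // XU + YU -> YU + YU
    a[8]  = (1.0 - ky) * fy * xU * yU;                 // XU + YU -> YU
    a[9]  = rp * ky * Qy * fy * xI * yU;               // XI + YU -> YI + YU + nz Z
    a[10] = (1.0 - rp * ky) * Qy * fy * xI * yU;       // XI + YU -> YI + nz Z
    a[11] = re * ky * (1.0 - Qy) * fy * xI * yU;       // XI + YU -> YU + YU
    a[12] = (1.0 - re * ky) * (1.0 - Qy) * fy * xI * yU; // XI + YU -> YU
    a[13] = rp * ky * fy * xU * yI;                    // XU + YI -> YI + YU
    a[14] = (1.0 - rp * ky) * fy * xU * yI;            // XU + YI -> YI
    a[15] = rp * rp * ky * Qy * fy * xI * yI;          // XI + YI -> YI + YU + nz Z
    a[16] = (1.0 - rp * rp * ky) * Qy * fy * xI * yI;  // XI + YI -> YI + nz Z
    a[17] = rp * re * ky * (1.0 - Qy) * fy * xI * yI;  // XI + YI -> YI + YU
    a[18] = (1.0 - rp * re * ky) * (1.0 - Qy) * fy * xI * yI; // XI + YI -> YI
    a[19] = dx * xU;                                   // XU -> 0
    a[20] = dx * xI;                                   // XI -> 0
    a[21] = dy * yU;                                   // YU -> 0
    a[22] = dy * yI;                                   // YI -> 0
    a[23] = dz * z;                                    // Z  -> 0
}

static void fill_deltas(double nz, double D[NCH][NSP]) {
    static const double base[NCH][NSP] = {
        {+1,  0,  0,  0,  0},   //  0 prey birth (infected parent, uninfected offspring)
        {+1,  0,  0,  0,  0},   //  1 prey birth (uninfected parent)
        { 0, -1,  0,  0,  0},   //  2 competition XI,XI
        {-1,  0,  0,  0,  0},   //  3 competition XI beats XU
        { 0, -1,  0,  0,  0},   //  4 competition XU beats XI
        {-1,  0,  0,  0,  0},   //  5 competition XU,XU
        {-1, +1,  0,  0, -1},   //  6 prey infection
        {-1,  0, +1,  0,  0},   //  7 predation XU+YU, offspring
        {-1,  0,  0,  0,  0},   //  8 predation XU+YU, no offspring
        { 0, -1,  0, +1,  1},   //  9 predation XI+YU, infection + offspring (z+nz)
        { 0, -1, -1, +1,  1},   // 10 predation XI+YU, infection, no offspring (z+nz)
        { 0, -1, +1,  0,  0},   // 11 predation XI+YU, exposure + offspring
        { 0, -1,  0,  0,  0},   // 12 predation XI+YU, exposure, no offspring
        {-1,  0, +1,  0,  0},   // 13 predation XU+YI, offspring
        {-1,  0,  0,  0,  0},   // 14 predation XU+YI, no offspring
        { 0, -1, +1,  0,  1},   // 15 predation XI+YI, reinfection + offspring (z+nz)
        { 0, -1,  0,  0,  1},   // 16 predation XI+YI, reinfection, no offspring (z+nz)
        { 0, -1, +1,  0,  0},   // 17 predation XI+YI, exposure + offspring
        { 0, -1,  0,  0,  0},   // 18 predation XI+YI, exposure, no offspring
        {-1,  0,  0,  0,  0},   // 19 death XU
        { 0, -1,  0,  0,  0},   // 20 death XI
        { 0,  0, -1,  0,  0},   // 21 death YU
        { 0,  0,  0, -1,  0},   // 22 death YI
        { 0,  0,  0,  0, -1}    // 23 death Z
    };
    for (int c = 0; c < NCH; ++c)
        for (int k = 0; k < NSP; ++k) {
            D[c][k] = base[c][k];
            // channels releasing parasite offspring scale the z entry by nz
            if (k == 4 && base[c][4] > 0.0) D[c][k] = nz;
        }
}

// Propensity vector and delta matrix at one state (for cross-checking the
// R-level reaction network).
RcppExport SEXP C_ssa_channels(SEXP state_, SEXP par_) {
BEGIN_RCPP
    NumericVector s(state_), P(par_);
    if (s.size() != NSP || P.size() != 14) stop("bad state/parameter length");
    double a[NCH], D[NCH][NSP];
    fill_propensities(REAL(s), REAL(P), a);
    fill_deltas(P[6], D);
    NumericVector props(NCH);
    NumericMatrix deltas(NCH, NSP);
    for (int c = 0; c < NCH; ++c) {
        props[c] = a[c];
        for (int k = 0; k < NSP; ++k) deltas(c, k) = D[c][k];
    }
    return List::create(_["propensity"] = props, _["delta"] = deltas);
END_RCPP
}

// Exact SSA path, recorded on a fixed sampling grid (plus the final state on
// absorption).  Uses R's RNG: the caller seeds with set.seed().
RcppExport SEXP C_ssa_run(SEXP state_, SEXP par_, SEXP tmax_, SEXP dt_,
                          SEXP maxevents_) {
BEGIN_RCPP
    NumericVector s0(state_), P(par_);
    const double tmax = as<double>(tmax_), dt = as<double>(dt_);
    const double max_events = as<double>(maxevents_);
    if (s0.size() != NSP || P.size() != 14) stop("bad state/parameter length");
    if (tmax <= 0 || dt <= 0) stop("t_max and sample_dt must be positive");

    double s[NSP];
    for (int k = 0; k < NSP; ++k) s[k] = s0[k];
    double a[NCH], D[NCH][NSP];
    fill_deltas(P[6], D);

    const long ngrid = (long)(tmax / dt + 1e-9) + 1; // grid 0, dt, ..., <= tmax
    std::vector<double> rec_t;
    std::vector<double> rec_s;
    rec_t.reserve(ngrid + 2);
    rec_s.reserve((ngrid + 2) * NSP);

    double t = 0.0;
    rec_t.push_back(0.0);
    for (int k = 0; k < NSP; ++k) rec_s.push_back(s[k]);
    long next_i = 1;
    bool absorbed = false;
    double n_events = 0.0;

    RNGScope scope;
    for (;;) {
        fill_propensities(s, REAL(P), a);
        double a0 = 0.0;
        for (int c = 0; c < NCH; ++c) a0 += a[c];
        if (a0 <= 0.0) { absorbed = true; break; }

        const double tnew = t + exp_rand() / a0;

        // record the (constant) pre-event state at every grid time passed
        while (next_i < ngrid && next_i * dt <= tnew) {
            rec_t.push_back(next_i * dt);
            for (int k = 0; k < NSP; ++k) rec_s.push_back(s[k]);
            ++next_i;
        }
        if (tnew > tmax) { t = tmax; break; }
        t = tnew;

        double u = unif_rand() * a0;
        int c = 0;
        for (; c < NCH - 1; ++c) { u -= a[c]; if (u <= 0.0) break; }
        for (int k = 0; k < NSP; ++k) s[k] += D[c][k];

        n_events += 1.0;
        if (n_events >= max_events)
            stop("event budget exceeded before t_max (%.0f events)", n_events);
        if (((long)n_events & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }

    if (absorbed) {
        // absorbing state: close the record at the absorption time
        if (t > rec_t.back()) {
            rec_t.push_back(t);
            for (int k = 0; k < NSP; ++k) rec_s.push_back(s[k]);
        }
    } else if (rec_t.back() < tmax) {
        rec_t.push_back(tmax);
        for (int k = 0; k < NSP; ++k) rec_s.push_back(s[k]);
    }

    const long n = (long)rec_t.size();
    NumericVector tt(n);
    NumericMatrix ss(n, NSP);
    for (long i = 0; i < n; ++i) {
        tt[i] = rec_t[i];
        for (int k = 0; k < NSP; ++k) ss(i, k) = rec_s[i * NSP + k];
    }
    return List::create(_["t"] = tt, _["states"] = ss,
                        _["absorbed"] = absorbed, _["n_events"] = n_events);
END_RCPP
}
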