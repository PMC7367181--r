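#include <Rcpp.h>
using namespace Rcpp;

// Direct-method (exact) stochastic simulation of the two-state expression
// system. Species: promoter state d (0 = OFF, 1 = ON), mRNA count m,
// protein count p. Reactions:
//   0: OFF -> ON          kon * (1 - d)
//   1: ON  -> OFF         koff * d
//   2: ON  -> ON + mRNA   km * d
//   3: mRNA -> 0          gm * m
//   4: mRNA -> mRNA + P   kp * m
//   5: P -> 0             gp * p
// Uses R's RNG (unif_rand) so that set.seed() on the R side makes every
// simulation bit-for-bit reproducible.

static inline int step(double kon, double koff, double km, double gm,
                       double kp, double gp,
                       int &d, double &m, double &p, double &t,
                       double t_end) {
    // returns 0 on a realized event, 1 if t_end reached, 2 if absorbed
    double a0 = kon * (1 - d) + koff * d + km * d + gm * m + kp * m + gp * p;
    if (a0 <= 0.0) return 2;
    double u = unif_rand();
    if (u <= 0.0) u = 1e-300;  // guard against log(0)
    double dt = -std::log(u) / a0;
    if (t + dt > t_end) { t = t_end; return 1; }
    t += dt;
    double r = unif_rand() * a0;
    double acc = kon * (1 - d);
    if (r < acc) { d = 1; return 0; }
    acc += koff * d;
    if (r < acc) { d = 0; return 0; }
    acc += km * d;
    if (r < acc) { m += 1; return 0; }
    acc += gm * m;
    if (r < acc) { m -= 1; return 0; }
    acc += kp * m;
    if (r < acc) { p += 1; return 0; }
    p -= 1;
    return 0;
}

// [[Rcpp::export(name = ".ssaTrajectoryCpp")]]
List ssaTrajectoryCpp(double kon, double koff, double km, double gm,
                      double kp, double gp, double t_end,
                      int d0, double m0, double p0, int max_events) {
    RNGScope scope;
    std::vector<double> times, ms, ps;
    std::vector<int> ds;
    int d = d0;
    double m = m0, p = p0, t = 0.0;
    times.push_back(0.0); ds.push_back(d); ms.push_back(m); ps.push_back(p);
    for (int i = 0; i < max_events; ++i) {
        int st = step(kon, koff, km, gm, kp, gp, d, m, p, t, t_end);
        if (st != 0) {
            return List::create(_["time"] = times, _["d_on"] = ds,
                                _["mrna"] = ms, _["protein"] = ps,
                                _["absorbed"] = (st == 2));
        }
        times.push_back(t); ds.push_back(d); ms.push_back(m); ps.push_back(p);
    }
    stop("trajectory exceeded max_events");
}

// [[Rcpp::export(name = ".ssaEndpointsCpp")]]
NumericVector ssaEndpointsCpp(double kon, double koff, double km, double gm,
                              double kp, double gp, double t_end,
                              IntegerVector d_init) {
    RNGScope scope;
    int n = d_init.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        int d = d_init[i];
        double m = 0.0, p = 0.0, t = 0.0;
        for (;;) {
            int st = step(kon, koff, km, gm, kp, gp, d, m, p, t, t_end);
            if (st != 0) break;
        }
        out[i] = p;
    }
    return out;
}

// Mean occupancy of the ON state over [0, t_end] for the promoter alone
// (time-weighted), used by exactness tests.
// [[Rcpp::export(name = ".ssaOccupancyCpp")]]
double ssaOccupancyCpp(double kon, double koff, double t_end, int d0) {
    RNGScope scope;
    int d = d0;
    double t = 0.0, on_time = 0.0;
    while (t < t_end) {
        double a = d ? koff : kon;
        if (a <= 0.0) { if (d) on_time += t_end - t; break; }
        double u = unif_rand();
        if (u <= 0.0) u = 1e-300;
        double dt = -std::log(u) / a;
        if (t + dt > t_end) dt = t_end - t;
        if (d) on_time += dt;
        t += dt;
        d = 1 - d;
    }
    return on_time / t_end;
}
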