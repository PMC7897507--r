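// Event-driven simulation of footprint-carrying SSB tetramers on a finite
// ssDNA lattice. Each protein record holds a position (0-based leftmost
// occupied nt) and a state (0 = bound-unwrapped, footprint n_b;
// 1 = wrapped, footprint n_w); footprints never overlap.
//
// Reorganisation modes:
//  * sliding = false: strict geometry. Nucleation needs a free run of n_b
//    nt (rate k_b*c per eligible start position); wrapping needs
//    n_w - n_b contiguous free nt immediately left or right of the bound
//    protein (side chosen uniformly when both fit). This mode exhibits
//    McGhee-von Hippel parking-lot jamming.
//  * sliding = true: ideal-reorganisation limit of fast 1D diffusion
//    (D ~ 300 nt^2/s equilibrates local gaps much faster than reactions):
//    free nucleotides are poolable, so nucleation runs at k_b*c per free
//    nt and the total wrap propensity is rationed to
//    k_w * min(N_bound, G/(n_w - n_b)) -- the stochastic counterpart of
//    the mean-field availability factor. After every event the gap
//    configuration is re-drawn uniformly (stars-and-bars), the stationary
//    law of single-file diffusion, keeping position-dependent quantities
//    (stimulation neighbourhood, event log) meaningful.
//
// Stimulated dissociation/unwrapping: each protein's effective rate is
// k + k_stim * theta_b_local with theta_b_local the fraction of the
// +/- w_stim nt flanking window covered by other bound-unwrapped protein
// ("fraction" rule, the local version of the mean-field law); the
// "binary" rule applies the full k + k_stim whenever any other
// bound-unwrapped protein lies within w_stim nt.
//
// All randomness goes through R's RNG, so results are reproducible via
// set.seed() in the calling R code.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Prot { int pos; int state; };

static inline double runif1() { return unif_rand(); }

class Lattice {
public:
  int L, n_b, n_w, w_stim;
  bool sliding, binary_stim, wrap_on;
  std::vector<Prot> prot;  // sorted by pos
  int free_nt;             // maintained incrementally

  int footprint(const Prot &p) const { return p.state ? n_w : n_b; }

  int gapBefore(size_t i) const {
    int lo = (i == 0) ? 0 : prot[i - 1].pos + footprint(prot[i - 1]);
    int hi = (i == prot.size()) ? L : prot[i].pos;
    return hi - lo;
  }

  void recountFree() {
    int occ = 0;
    for (size_t i = 0; i < prot.size(); ++i) occ += footprint(prot[i]);
    free_nt = L - occ;
  }

  void checkInvariant() const {
    for (size_t i = 0; i + 1 < prot.size(); ++i)
      if (prot[i].pos + footprint(prot[i]) > prot[i + 1].pos)
        stop("internal invariant violation: overlapping footprints");
    if (!prot.empty() &&
        (prot.front().pos < 0 ||
         prot.back().pos + footprint(prot.back()) > L))
      stop("internal invariant violation: protein outside lattice");
  }

  // bound-unwrapped coverage of the +/- w_stim window flanking protein i,
  // excluding i; walks sorted neighbours only
  double localThetaB(size_t i) const {
    int lo = prot[i].pos - w_stim;
    int hi = prot[i].pos + footprint(prot[i]) + w_stim;
    int covered = 0; bool any = false;
    for (size_t j = i; j-- > 0; ) {
      if (prot[j].pos + n_w < lo && prot[j].pos + footprint(prot[j]) < lo)
        break;
      if (prot[j].state != 0) continue;
      int a = std::max(prot[j].pos, lo);
      int b = std::min(prot[j].pos + n_b, hi);
      if (b > a) { covered += b - a; any = true; }
    }
    for (size_t j = i + 1; j < prot.size(); ++j) {
      if (prot[j].pos > hi) break;
      if (prot[j].state != 0) continue;
      int a = std::max(prot[j].pos, lo);
      int b = std::min(prot[j].pos + n_b, hi);
      if (b > a) { covered += b - a; any = true; }
    }
    if (binary_stim) return any ? 1.0 : 0.0;
    return std::min(1.0, covered / (2.0 * w_stim));
  }

  // redraw the gap configuration uniformly: choose N bar positions among
  // G + N slots by sequential selection sampling, O(G + N)
  void resampleGaps() {
    size_t N = prot.size();
    if (N == 0) return;
    int G = free_nt;
    int total = G + (int)N;
    int need = (int)N;
    int pos = 0;        // running lattice position
    size_t i = 0;       // next protein to place
    for (int slot = 0; slot < total && need > 0; ++slot) {
      if (runif1() * (total - slot) < need) {
        prot[i].pos = pos;
        pos += footprint(prot[i]);
        ++i; --need;
      } else {
        ++pos;          // a free nucleotide
      }
    }
  }
};

// [[Rcpp::export(name = ".gillespie_run")]]
List gillespie_run(int L, double conc, List pars, double t_max,
                   bool sliding, std::string stimulation_rule,
                   double sample_dt, int w_stim, bool log_events) {
  RNGScope scope;
  Lattice lat;
  lat.L = L;
  lat.n_b = as<int>(pars["n_b"]);
  lat.n_w = as<int>(pars["n_w"]);
  lat.w_stim = w_stim;
  lat.sliding = sliding;
  lat.binary_stim = (stimulation_rule == "binary");
  lat.wrap_on = as<bool>(pars["wrapping_active"]);
  lat.free_nt = L;
  const double k_b = as<double>(pars["k_b"]);
  const double k_off = as<double>(pars["k_off"]);
  const double k_w = as<double>(pars["k_w"]);
  const double k_unw = as<double>(pars["k_unw"]);
  const double k_off_stim = as<double>(pars["k_off_stim"]);
  const double k_unw_stim = as<double>(pars["k_unw_stim"]);
  if (L < lat.n_b) stop("lattice shorter than the bound footprint");

  const double x_b = as<double>(pars["x_b"]);
  const double dx_wrap = as<double>(pars["dx_wrap"]);  // nm per wrap event
  const int extra = lat.n_w - lat.n_b;

  std::vector<double> s_time, s_thb, s_thw;
  std::vector<double> e_time, e_pos, e_dx;
  std::vector<int> e_type;  // 1 bind, 2 wrap, 3 unwrap, 4 dissociate

  double t = 0.0, t_next_sample = 0.0;
  long guard = 0;
  std::vector<double> a_wrap, a_off, a_unw, bind_gap_w;
  std::vector<int> wrap_side;
  while (true) {
    if (++guard > 100000000L) stop("event budget exceeded");
    size_t N = lat.prot.size();
    double a_bind = 0.0;
    if (lat.sliding) {
      a_bind = (lat.free_nt >= lat.n_b) ? k_b * conc * lat.free_nt : 0.0;
    } else {
      bind_gap_w.assign(N + 1, 0.0);
      for (size_t g = 0; g <= N; ++g) {
        int gap = lat.gapBefore(g);
        if (gap >= lat.n_b) {
          bind_gap_w[g] = gap - lat.n_b + 1;
          a_bind += bind_gap_w[g];
        }
      }
      a_bind *= k_b * conc;
    }
    a_wrap.assign(N, 0.0); a_off.assign(N, 0.0); a_unw.assign(N, 0.0);
    wrap_side.assign(N, 0);
    double A_wrap = 0, A_off = 0, A_unw = 0;
    int n_bound = 0;
    for (size_t i = 0; i < N; ++i) n_bound += (lat.prot[i].state == 0);
    double wrap_ration = 1.0;
    if (lat.sliding && lat.wrap_on && n_bound > 0)
      wrap_ration = std::min(1.0, lat.free_nt / (double)extra / n_bound);
    for (size_t i = 0; i < N; ++i) {
      double thb = lat.localThetaB(i);
      if (lat.prot[i].state == 0) {
        double koff_eff = k_off + (lat.wrap_on ? k_off_stim * thb : 0.0);
        a_off[i] = koff_eff; A_off += koff_eff;
        if (lat.wrap_on && k_w > 0) {
          if (lat.sliding) {
            if (lat.free_nt >= extra) {
              a_wrap[i] = k_w * wrap_ration; A_wrap += a_wrap[i];
              wrap_side[i] = 2;
            }
          } else {
            bool left = lat.gapBefore(i) >= extra;
            bool right = lat.gapBefore(i + 1) >= extra;
            if (left || right) {
              a_wrap[i] = k_w; A_wrap += k_w;
              wrap_side[i] = (left && right) ? 2 : (left ? -1 : 1);
            }
          }
        }
      } else {
        double kunw_eff = k_unw + (lat.wrap_on ? k_unw_stim * thb : 0.0);
        a_unw[i] = kunw_eff; A_unw += kunw_eff;
      }
    }
    double A = a_bind + A_wrap + A_off + A_unw;
    double dt = (A > 0) ? -std::log(std::max(runif1(), 1e-300)) / A
                        : (t_max - t + 1.0);
    double t_new = t + dt;
    while (t_next_sample <= std::min(t_new, t_max) + 1e-12) {
      double thb = 0, thw = 0;
      for (size_t i = 0; i < N; ++i) {
        if (lat.prot[i].state == 0) thb += lat.n_b; else thw += lat.n_w;
      }
      s_time.push_back(t_next_sample);
      s_thb.push_back(thb / L);
      s_thw.push_back(thw / L);
      t_next_sample += sample_dt;
      if (t_next_sample > t_max + 1e-9) break;
    }
    if (t_new > t_max || A <= 0) break;
    t = t_new;
    double u = runif1() * A;
    if (u < a_bind) {
      // nucleation
      size_t g; int newpos;
      if (lat.sliding) {
        // reorganisation makes every free nt a nucleation point: insert at
        // a uniformly chosen slot; the post-event gap redraw places it
        g = (size_t)std::min((double)N, std::floor(runif1() * (N + 1)));
        newpos = 0;  // provisional, fixed by resampleGaps()
      } else {
        double v = runif1() * (a_bind / (k_b * conc)); g = 0;
        while (g + 1 < bind_gap_w.size() && v >= bind_gap_w[g]) {
          v -= bind_gap_w[g]; ++g;
        }
        while (bind_gap_w[g] <= 0 && g > 0) --g;  // numeric edge guard
        int lo = (g == 0) ? 0
          : lat.prot[g - 1].pos + lat.footprint(lat.prot[g - 1]);
        int cap = lat.gapBefore(g) - lat.n_b;
        newpos = lo + std::min((int)(runif1() * (cap + 1)), cap);
      }
      Prot p; p.pos = newpos; p.state = 0;
      lat.prot.insert(lat.prot.begin() + g, p);
      lat.free_nt -= lat.n_b;
      if (lat.sliding) lat.resampleGaps();
      if (log_events) {
        e_time.push_back(t); e_type.push_back(1);
        e_pos.push_back(lat.prot[g].pos); e_dx.push_back(x_b * lat.n_b);
      }
    } else if (u < a_bind + A_wrap) {
      double v = u - a_bind; size_t i = 0;
      while (i + 1 < N && v >= a_wrap[i]) { v -= a_wrap[i]; ++i; }
      while (a_wrap[i] <= 0 && i > 0) --i;  // numeric edge guard
      if (lat.sliding) {
        // the free-nt pool has capacity (propensity was rationed on it);
        // reorganisation gathers the extra nucleotides
        lat.prot[i].state = 1;
        lat.free_nt -= extra;
        lat.resampleGaps();
      } else {
        bool useLeft;
        if (wrap_side[i] == 2) useLeft = runif1() < 0.5;
        else useLeft = wrap_side[i] == -1;
        if (useLeft) lat.prot[i].pos -= extra;
        lat.prot[i].state = 1;
        lat.free_nt -= extra;
      }
      if (log_events) {
        e_time.push_back(t); e_type.push_back(2);
        e_pos.push_back(lat.prot[i].pos); e_dx.push_back(dx_wrap);
      }
    } else if (u < a_bind + A_wrap + A_off) {
      double v = u - a_bind - A_wrap; size_t i = 0;
      while (i + 1 < N && v >= a_off[i]) { v -= a_off[i]; ++i; }
      while (a_off[i] <= 0 && i > 0) --i;  // numeric edge guard
      int pos = lat.prot[i].pos;
      lat.prot.erase(lat.prot.begin() + i);
      lat.free_nt += lat.n_b;
      if (log_events) {
        e_time.push_back(t); e_type.push_back(4);
        e_pos.push_back(pos); e_dx.push_back(-x_b * lat.n_b);
      }
    } else {
      double v = u - a_bind - A_wrap - A_off; size_t i = 0;
      while (i + 1 < N && v >= a_unw[i]) { v -= a_unw[i]; ++i; }
      while (a_unw[i] <= 0 && i > 0) --i;  // numeric edge guard
      if (runif1() < 0.5) lat.prot[i].pos += extra;  // keep right end
      lat.prot[i].state = 0;
      lat.free_nt += extra;
      if (log_events) {
        e_time.push_back(t); e_type.push_back(3);
        e_pos.push_back(lat.prot[i].pos); e_dx.push_back(-dx_wrap);
      }
    }
    if (lat.sliding) lat.resampleGaps();
    lat.checkInvariant();
  }

  CharacterVector type_str(e_type.size());
  for (size_t i = 0; i < e_type.size(); ++i) {
    type_str[i] = e_type[i] == 1 ? "bind" : e_type[i] == 2 ? "wrap"
      : e_type[i] == 3 ? "unwrap" : "dissociate";
  }
  return List::create(
    _["time"] = s_time, _["theta_b"] = s_thb, _["theta_w"] = s_thw,
    _["event_time"] = e_time, _["event_type"] = type_str,
    _["event_pos"] = e_pos, _["event_dx"] = e_dx,
    _["n_final"] = (int)lat.prot.size());
}
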