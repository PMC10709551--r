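#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// D3Q19 stencil. Ordering MUST match velocity_set() on the R side:
// rest, 6 face directions, 12 edge directions, opposite pairs adjacent.
static const int CX[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
static const int CY[19] = {0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1};
static const int CZ[19] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1};
static const int OPP[19]= {0, 2, 1, 4, 3, 6, 5, 8, 7,10, 9,12,11,14,13,16,15,18,17};
static const double W[19] = {
  1.0/3.0,
  1.0/18.0, 1.0/18.0, 1.0/18.0, 1.0/18.0, 1.0/18.0, 1.0/18.0,
  1.0/36.0, 1.0/36.0, 1.0/36.0, 1.0/36.0, 1.0/36.0, 1.0/36.0,
  1.0/36.0, 1.0/36.0, 1.0/36.0, 1.0/36.0, 1.0/36.0, 1.0/36.0
};

// Second-order Maxwell-Boltzmann equilibrium.
static inline void eq19(double rho, double ux, double uy, double uz,
                        double *out) {
  const double usq = ux * ux + uy * uy + uz * uz;
  for (int i = 0; i < 19; ++i) {
    const double cu = CX[i] * ux + CY[i] * uy + CZ[i] * uz;
    out[i] = W[i] * rho * (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * usq);
  }
}

static inline void moments(const double *f, double &rho,
                           double &ux, double &uy, double &uz) {
  rho = 0.0; ux = 0.0; uy = 0.0; uz = 0.0;
  for (int i = 0; i < 19; ++i) {
    rho += f[i];
    ux += CX[i] * f[i];
    uy += CY[i] * f[i];
    uz += CZ[i] * f[i];
  }
  ux /= rho; uy /= rho; uz /= rho;
}

// Fused BGK time stepper.
//
// Neighbour codes in `neigh` (19 x n, 1-based where positive):
//   > 0  : index of the wet neighbour receiving population i
//   -1   : static wall link (halfway bounce-back)
//   -2   : inlet exterior link (moving-wall bounce-back at the cap plane)
//   -3   : outlet exterior link (overwritten by the outlet closure)
// Update order per step: collide -> stream/walls/inlets -> outlets.
// Flow samples and diagnostics are taken from the post-step state.
// [[Rcpp::export]]
List cpp_run_lbm(NumericMatrix f0,
                 IntegerMatrix neigh,
                 IntegerVector kind,        // 0 fluid, 1 inlet, 2 outlet
                 IntegerVector iolet,       // 1-based iolet id, 0 = none
                 NumericVector weight,      // inlet profile weight in [0,1]
                 NumericMatrix iolet_dir,   // 3 x n_iolets flow/velocity direction
                 NumericMatrix inlet_speed, // n_steps x n_iolets, lattice units
                 NumericVector rho_out,     // per iolet (used for outlets)
                 IntegerVector interior,    // 1-based interior neighbour (outlet sites)
                 double tau,
                 int n_steps,
                 int cadence,
                 IntegerVector snapshot_steps,
                 double steady_tol,
                 int steady_every) {
  const int n = f0.ncol();
  const int n_io = iolet_dir.ncol();
  if (f0.nrow() != 19) stop("f must be a 19 x n matrix");

  std::vector<double> f(f0.begin(), f0.end());
  std::vector<double> fn(19 * (size_t)n);
  std::vector<double> rho_site(n);
  std::vector<int> out_sites;
  for (int s = 0; s < n; ++s) if (kind[s] == 2) out_sites.push_back(s);

  const double omega = 1.0 / tau;
  bool diverged = false;
  int div_site = -1, div_step = -1;

  std::vector<int> sample_steps;
  std::vector<double> mass_log, umax_log;
  std::vector< std::vector<double> > flow_log; // per sample, length n_io
  List snapshots;
  std::vector<int> snap_steps_done;
  int snap_ptr = 0;

  std::vector<double> uprev;
  if (steady_tol > 0) uprev.assign(3 * (size_t)n, 0.0);
  bool converged = false;
  int steps_run = 0;

  double feq[19];

  const int *neigh_p = neigh.begin();
  double fstar[19];

  for (int step = 1; step <= n_steps && !diverged; ++step) {
    // --- fused collide + stream + walls + inlets (push) ---
    for (int s = 0; s < n; ++s) {
      double *fs = &f[19 * (size_t)s];
      double rho, ux, uy, uz;
      moments(fs, rho, ux, uy, uz);
      if (!std::isfinite(rho) || rho <= 0.0 ||
          !std::isfinite(ux) || !std::isfinite(uy) || !std::isfinite(uz)) {
        diverged = true; div_site = s + 1; div_step = step; break;
      }
      rho_site[s] = rho;
      eq19(rho, ux, uy, uz, feq);
      for (int i = 0; i < 19; ++i) fstar[i] = fs[i] - omega * (fs[i] - feq[i]);

      const int *ns = neigh_p + 19 * (size_t)s;
      const int io = iolet[s] - 1;
      for (int i = 0; i < 19; ++i) {
        const int code = ns[i];
        if (code > 0) {
          fn[19 * (size_t)(code - 1) + i] = fstar[i];
        } else if (code == -1) {
          fn[19 * (size_t)s + OPP[i]] = fstar[i];
        } else if (code == -2) {
          const double v = inlet_speed(step - 1, io) * weight[s];
          const double cu = CX[i] * iolet_dir(0, io) +
                            CY[i] * iolet_dir(1, io) +
                            CZ[i] * iolet_dir(2, io);
          fn[19 * (size_t)s + OPP[i]] =
            fstar[i] - 6.0 * W[i] * rho * cu * v;
        }
        // code == -3: outlet closure below rewrites the whole site
      }
    }
    if (diverged) break;

    // --- outlets: equilibrium at fixed density, extrapolated velocity ---
    for (size_t k = 0; k < out_sites.size(); ++k) {
      const int s = out_sites[k];
      const int nb = interior[s] - 1;
      double rho, ux, uy, uz;
      moments(&fn[19 * (size_t)nb], rho, ux, uy, uz);
      eq19(rho_out[iolet[s] - 1], ux, uy, uz, &fn[19 * (size_t)s]);
    }

    f.swap(fn);
    steps_run = step;

    const bool do_sample = (cadence > 0) && (step % cadence == 0 || step == n_steps);
    const bool do_snap = (snap_ptr < snapshot_steps.size()) &&
                         (step == snapshot_steps[snap_ptr]);
    const bool do_steady = (steady_tol > 0) && (step % steady_every == 0);

    if (do_sample || do_steady) {
      double mass = 0.0, umax2 = 0.0, du2max = 0.0;
      std::vector<double> q(n_io, 0.0);
      for (int s = 0; s < n; ++s) {
        double rho, ux, uy, uz;
        moments(&f[19 * (size_t)s], rho, ux, uy, uz);
        mass += rho;
        const double u2 = ux * ux + uy * uy + uz * uz;
        if (u2 > umax2) umax2 = u2;
        const int io = iolet[s] - 1;
        if (io >= 0) {
          q[io] += ux * iolet_dir(0, io) + uy * iolet_dir(1, io) +
                   uz * iolet_dir(2, io);
        }
        if (do_steady) {
          const double dx_ = ux - uprev[3 * (size_t)s];
          const double dy_ = uy - uprev[3 * (size_t)s + 1];
          const double dz_ = uz - uprev[3 * (size_t)s + 2];
          const double d2 = dx_ * dx_ + dy_ * dy_ + dz_ * dz_;
          if (d2 > du2max) du2max = d2;
          uprev[3 * (size_t)s] = ux;
          uprev[3 * (size_t)s + 1] = uy;
          uprev[3 * (size_t)s + 2] = uz;
        }
      }
      if (do_sample) {
        sample_steps.push_back(step);
        mass_log.push_back(mass);
        umax_log.push_back(std::sqrt(umax2));
        flow_log.push_back(q);
      }
      if (do_steady && step > steady_every) {
        const double scale = std::sqrt(umax2);
        if (std::sqrt(du2max) <= steady_tol * (scale > 0 ? scale : 1.0)) {
          converged = true;
        }
      }
    }

    if (do_snap) {
      NumericMatrix snap(19, n);
      std::copy(f.begin(), f.end(), snap.begin());
      snapshots.push_back(snap);
      snap_steps_done.push_back(step);
      ++snap_ptr;
    }
    if (converged) break;
  }

  NumericMatrix ffinal(19, n);
  std::copy(f.begin(), f.end(), ffinal.begin());
  const int ns = sample_steps.size();
  NumericMatrix flow(ns, n_io);
  for (int r = 0; r < ns; ++r)
    for (int c = 0; c < n_io; ++c) flow(r, c) = flow_log[r][c];

  return List::create(
    _["f"] = ffinal,
    _["sample_steps"] = wrap(sample_steps),
    _["flow"] = flow,
    _["mass"] = wrap(mass_log),
    _["umax"] = wrap(umax_log),
    _["snapshots"] = snapshots,
    _["snapshot_steps"] = wrap(snap_steps_done),
    _["steps_run"] = steps_run,
    _["converged"] = converged,
    _["diverged"] = diverged,
    _["div_site"] = div_site,
    _["div_step"] = div_step);
}

// Connected components over wet sites (positive neighbour codes only).
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerMatrix neigh) {
  const int n = neigh.ncol();
  IntegerVector comp(n, 0);
  int ncomp = 0;
  std::vector<int> stack;
  for (int seed = 0; seed < n; ++seed) {
    if (comp[seed] != 0) continue;
    ++ncomp;
    comp[seed] = ncomp;
    stack.push_back(seed);
    while (!stack.empty()) {
      const int s = stack.back(); stack.pop_back();
      for (int i = 0; i < 19; ++i) {
        const int code = neigh(i, s);
        if (code > 0 && comp[code - 1] == 0) {
          comp[code - 1] = ncomp;
          stack.push_back(code - 1);
        }
      }
    }
  }
  return comp;
}
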