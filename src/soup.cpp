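#include <Rcpp.h>
using namespace Rcpp;

// Euler--Maruyama integrator for the soup ensemble.
//
// State per subsystem: position/velocity in d dimensions plus a 3-vector of
// electrochemical states driven by a coupled Lorenz-form flow.  All right-hand
// sides are evaluated on the pre-step state (forward Euler); unit-variance
// Gaussian increments scaled by noise_sd*sqrt(dt) enter the velocity and
// electrochemical equations.  Noise is drawn from R's RNG (velocity block
// first, then the electrochemical block, both column-major) so that runs are
// reproducible from set.seed() and a single step matches step().
//
// Contact adjacency (distance <= coupling_radius, columns of closed
// subsystems zeroed) is recomputed from the current positions at every step.
// Pairwise distances in the force law are clamped below at dist_clamp;
// clamped encounters are counted and reported.

// [[Rcpp::export]]
List soup_integrate_cpp(NumericMatrix pos0, NumericMatrix vel0,
                        NumericMatrix chem0, NumericVector kappa,
                        LogicalVector closed, List par,
                        double t0, int n_steps, int save_every) {
  const int n = pos0.nrow(), d = pos0.ncol();
  const double dt          = as<double>(par["dt"]);
  const double radius      = as<double>(par["coupling_radius"]);
  const double sigma       = as<double>(par["sigma"]);
  const double rho_l       = as<double>(par["rayleigh"]);
  const double beta        = as<double>(par["beta"]);
  const double k_rep       = as<double>(par["repulsion_strength"]);
  const double k_att       = as<double>(par["attraction_strength"]);
  const double visc        = as<double>(par["viscosity_coeff"]);
  const double k_well      = as<double>(par["well_stiffness"]);
  const double noise_sd    = as<double>(par["noise_sd"]);
  const double clamp       = as<double>(par["dist_clamp"]);
  const double coh2        = as<double>(par["coherence_scale"]) *
                             as<double>(par["coherence_scale"]);
  const double screen      = as<double>(par["repulsion_screen"]);
  const double sqdt = std::sqrt(dt);
  const double r2max = radius * radius;

  std::vector<double> pos(pos0.begin(), pos0.end());
  std::vector<double> vel(vel0.begin(), vel0.end());
  std::vector<double> chem(chem0.begin(), chem0.end());
  std::vector<double> force(n * d), avg(n * 3), flow(n * 3);
  std::vector<int> ncount(n);

  const int n_frames = n_steps / save_every + 1;
  NumericVector times(n_frames);
  NumericVector P(n_frames * n * d), V(n_frames * n * d), C(n_frames * n * 3);
  long clamped = 0;

  // frames stored as [frame, subsystem, coord], column-major
  auto save_frame = [&](int f, double t) {
    times[f] = t;
    for (int c = 0; c < d; ++c)
      for (int i = 0; i < n; ++i) {
        P[f + n_frames * (i + n * c)] = pos[i + n * c];
        V[f + n_frames * (i + n * c)] = vel[i + n * c];
      }
    for (int c = 0; c < 3; ++c)
      for (int i = 0; i < n; ++i)
        C[f + n_frames * (i + n * c)] = chem[i + n * c];
  };
  save_frame(0, t0);

  for (int s = 0; s < n_steps; ++s) {
    // pairwise pass: forces and local-average accumulators
    std::fill(force.begin(), force.end(), 0.0);
    std::fill(ncount.begin(), ncount.end(), 0);
    for (int c = 0; c < 3; ++c)
      for (int i = 0; i < n; ++i) avg[i + n * c] = chem[i + n * c];
    for (int i = 0; i < n; ++i) ncount[i] = 1;  // self in local average

    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double r2 = 0.0, dx[8];
        for (int c = 0; c < d; ++c) {
          dx[c] = pos[i + n * c] - pos[j + n * c];
          r2 += dx[c] * dx[c];
        }
        double r = std::sqrt(r2);
        if (r < clamp) { r = clamp; r2 = clamp * clamp; ++clamped; }
        // contact adjacency: within radius; closed columns removed
        if (r2 <= r2max) {
          if (!closed[j]) {  // j influences i
            ++ncount[i];
            for (int c = 0; c < 3; ++c) avg[i + n * c] += chem[j + n * c];
          }
          if (!closed[i]) {  // i influences j
            ++ncount[j];
            for (int c = 0; c < 3; ++c) avg[j + n * c] += chem[i + n * c];
          }
        }
        // inverse-square repulsion; short-range attraction gated by the
        // coherence of the third electrochemical states (attract when
        // similar, repel when not).  The bond is a reciprocal
        // electrochemical exchange: a functionally closed subsystem cannot
        // exert electrochemical influence, so pairs involving one form no
        // bond at all (symmetric, preserving Newton's third law).
        double gr = r / radius;
        // repulsion: inverse-square in the near field, screened beyond a
        // few coupling radii (all interactions are short-range)
        double fmag = k_rep / r2 * std::exp(-gr * gr / (2 * screen * screen));
        if (!closed[i] && !closed[j]) {
          double dz = chem[i + 2 * n] - chem[j + 2 * n];
          double coh = (coh2 - dz * dz) / (coh2 + dz * dz);
          fmag -= k_att * coh * gr * std::exp(-0.5 * gr * gr);
        }
        for (int c = 0; c < d; ++c) {
          double fc = fmag * dx[c] / r;
          force[i + n * c] += fc;   // Newton's third law: equal and opposite
          force[j + n * c] -= fc;
        }
      }
    }

    // electrochemical flow: Lorenz form on the local average, rate kappa
    for (int i = 0; i < n; ++i) {
      const double x1 = chem[i], x2 = chem[i + n], x3 = chem[i + 2 * n];
      const double m = 1.0 / ncount[i];
      const double v1 = avg[i] * m, v2 = avg[i + n] * m;
      flow[i]         = kappa[i] * sigma * (v2 - x1);
      flow[i + n]     = kappa[i] * (rho_l * v1 - x2 - v1 * x3);
      flow[i + 2 * n] = kappa[i] * (v1 * x2 - beta * x3);
    }

    // Euler--Maruyama update (RHS from pre-step state)
    NumericVector xi_v = rnorm(n * d);
    NumericVector xi_c = rnorm(n * 3);
    for (int c = 0; c < d; ++c)
      for (int i = 0; i < n; ++i) {
        const int idx = i + n * c;
        const double pos_old = pos[idx];
        pos[idx] += vel[idx] * dt;
        vel[idx] += (force[idx] - visc * vel[idx] - k_well * pos_old) * dt +
                    noise_sd * sqdt * xi_v[idx];
      }
    for (int c = 0; c < 3; ++c)
      for (int i = 0; i < n; ++i) {
        const int idx = i + n * c;
        chem[idx] += flow[idx] * dt + noise_sd * sqdt * xi_c[idx];
      }

    const double t = t0 + (s + 1) * dt;
    for (int i = 0; i < n; ++i) {
      bool bad = false;
      for (int c = 0; c < d; ++c)
        if (!std::isfinite(pos[i + n * c]) || !std::isfinite(vel[i + n * c]))
          bad = true;
      for (int c = 0; c < 3; ++c)
        if (!std::isfinite(chem[i + n * c])) bad = true;
      if (bad)
        stop("integration blow-up: non-finite state at t = %f for subsystem %d",
             t, i + 1);
    }

    if ((s + 1) % save_every == 0) save_frame((s + 1) / save_every, t);
  }

  P.attr("dim") = IntegerVector::create(n_frames, n, d);
  V.attr("dim") = IntegerVector::create(n_frames, n, d);
  C.attr("dim") = IntegerVector::create(n_frames, n, 3);
  return List::create(_["times"] = times, _["positions"] = P,
                      _["velocities"] = V, _["chem"] = C,
                      _["n_clamped"] = (double)clamped);
}

// Euler--Maruyama simulation of a linear standard-form flow
// dx = -(Gamma + R) %*% grad G dt + sqrt(2 Gamma) dW, quadratic G = x'Px/2,
// thinned to approximately independent samples.  drift = -(Gamma+R) %*% P.
// [[Rcpp::export]]
NumericMatrix ou_sample_cpp(NumericMatrix drift, NumericMatrix diff_chol,
                            double dt, int n_samples, int thin, int burn) {
  const int d = drift.nrow();
  NumericMatrix out(n_samples, d);
  std::vector<double> x(d, 0.0), xn(d);
  const double sqdt = std::sqrt(dt);
  long total = (long)burn + (long)n_samples * thin;
  int taken = 0;
  for (long s = 0; s < total; ++s) {
    NumericVector xi = rnorm(d);
    for (int i = 0; i < d; ++i) {
      double dr = 0.0, no = 0.0;
      for (int j = 0; j < d; ++j) {
        dr += drift(i, j) * x[j];
        no += diff_chol(i, j) * xi[j];
      }
      xn[i] = x[i] + dr * dt + sqdt * no;
    }
    x = xn;
    if (s >= burn && ((s - burn + 1) % thin == 0)) {
      for (int i = 0; i < d; ++i) out(taken, i) = x[i];
      ++taken;
      if (taken == n_samples) break;
    }
  }
  return out;
}
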