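#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Photon-level simulation of one molecule diffusing through a 3D-Gaussian
// confocal volume while switching FRET states (CTMC), under ideal ALEX.
//
// All arguments in SI-ish units: seconds, micrometres, photons per second.
// Photons are generated by thinning an inhomogeneous Poisson process whose
// rate is piecewise-constant over propagation steps; steps are split at CTMC
// transition times so the emitting state is constant within a step.  The
// laser phase is resolved per photon from its timestamp (exact for the
// ideal instantaneous alternation modelled here).
//
// Far from the volume (scaled distance u = sqrt(2r_xy^2/wxy^2 + 2z^2/wz^2)
// > 4.5, detection probability < 1e-8) the propagation step is lengthened,
// bounded so that a 4-sigma per-axis displacement cannot reach the u = 4
// surface.  Brownian increments are exact at any step size, so diffusion
// statistics are unaffected; only photon thinning needs the fine step.
//
// Uses R's RNG throughout so results are reproducible via set.seed().

// [[Rcpp::export]]
List cpp_simulate_stream(double duration, double dt, double D,
    double wxy, double wz, double boxHalf,
    double peakRate, double directRate, double alexHalf,
    NumericVector Estates, NumericMatrix Q,
    double bleachD, double bleachA,
    NumericVector pos0, int state0, bool adaptive) {

  std::vector<double> pt;       // photon times (s)
  std::vector<int> pch, pex, pst, pda, paa;

  double t = 0.0, x = pos0[0], y = pos0[1], z = pos0[2];
  int s = state0;               // 0-based state index
  const int K = Estates.size();
  const bool alex = alexHalf > 0.0;
  const double dutyD = alex ? 0.5 : 1.0;

  double kexit = -Q(s, s);
  double tTrans = (kexit > 0) ? t + R::rexp(1.0 / kexit) : R_PosInf;

  // first-order bleaching via inverted cumulative hazards
  double HD = 0.0, HA = 0.0;
  double thD = (bleachD > 0) ? R::rexp(1.0) : R_PosInf;
  double thA = (bleachA > 0) ? R::rexp(1.0) : R_PosInf;
  double tBleachD = R_PosInf, tBleachA = R_PosInf;

  const double wxy2 = wxy * wxy, wz2 = wz * wz;

  while (t < duration) {
    double q2 = 2.0 * (x * x + y * y) / wxy2 + 2.0 * z * z / wz2;
    double psf = std::exp(-q2);

    double h = dt;
    if (adaptive) {
      double u = std::sqrt(q2);
      if (u > 4.5) {
        double margin = (u - 4.0) * wxy / 1.41421356237;  // conservative scale
        double hFar = margin * margin / (32.0 * D);       // 4 sd per axis
        if (hFar > h) h = std::min(hFar, 0.02);
      }
    }
    double tEnd = std::min(t + h, duration);
    bool transNow = false;
    if (tTrans < tEnd) { tEnd = tTrans; transNow = true; }
    h = tEnd - t;
    if (h <= 0) { t = tEnd; h = 0; }

    if (h > 0) {
      // bleach times (hazard proportional to local excitation)
      if (bleachD > 0 && tBleachD == R_PosInf) {
        double hz = bleachD * psf * dutyD;
        if (hz > 0 && HD + hz * h >= thD) tBleachD = t + (thD - HD) / hz;
        HD += hz * h;
      }
      if (bleachA > 0 && tBleachA == R_PosInf) {
        double hz = bleachA * psf;
        if (hz > 0 && HA + hz * h >= thA) tBleachA = t + (thA - HA) / hz;
        HA += hz * h;
      }

      // donor-excitation photons (FRET-split between channels)
      double lamD = peakRate * psf;
      if (lamD > 0) {
        int nD = (int) R::rpois(lamD * h);
        for (int i = 0; i < nD; ++i) {
          double tp = t + unif_rand() * h;
          if (alex && ((long long)(tp / alexHalf)) % 2 != 0) continue;
          if (tp >= tBleachD) continue;                   // donor dark
          bool aAlive = tp < tBleachA;
          double E = Estates[s];
          int ch = (aAlive && unif_rand() < E) ? 2 : 1;   // bleach reroutes to donor
          pt.push_back(tp); pch.push_back(ch); pex.push_back(1);
          pst.push_back(s + 1); pda.push_back(1); paa.push_back(aAlive ? 1 : 0);
        }
      }
      // acceptor-excitation photons (direct excitation, acceptor channel)
      if (alex && directRate > 0) {
        double lamA = directRate * psf;
        int nA = (int) R::rpois(lamA * h);
        for (int i = 0; i < nA; ++i) {
          double tp = t + unif_rand() * h;
          if (((long long)(tp / alexHalf)) % 2 != 1) continue;
          if (tp >= tBleachA) continue;
          pt.push_back(tp); pch.push_back(2); pex.push_back(2);
          pst.push_back(s + 1); pda.push_back(tp < tBleachD ? 1 : 0);
          paa.push_back(1);
        }
      }

      // Brownian step with periodic re-injection
      double sdStep = std::sqrt(2.0 * D * h);
      x += norm_rand() * sdStep;
      y += norm_rand() * sdStep;
      z += norm_rand() * sdStep;
      double span = 2.0 * boxHalf;
      if (x >  boxHalf) x -= span * std::ceil((x - boxHalf) / span);
      if (x < -boxHalf) x += span * std::ceil((-boxHalf - x) / span);
      if (y >  boxHalf) y -= span * std::ceil((y - boxHalf) / span);
      if (y < -boxHalf) y += span * std::ceil((-boxHalf - y) / span);
      if (z >  boxHalf) z -= span * std::ceil((z - boxHalf) / span);
      if (z < -boxHalf) z += span * std::ceil((-boxHalf - z) / span);
    }

    t = tEnd;
    if (transNow) {
      double u = unif_rand() * kexit, acc = 0.0;
      int snew = s;
      for (int j = 0; j < K; ++j) {
        if (j == s) continue;
        acc += Q(s, j);
        if (u <= acc) { snew = j; break; }
      }
      s = snew;
      kexit = -Q(s, s);
      tTrans = (kexit > 0) ? t + R::rexp(1.0 / kexit) : R_PosInf;
    }
  }

  // time-order the photons (stable for determinism)
  const size_t n = pt.size();
  std::vector<size_t> idx(n);
  for (size_t i = 0; i < n; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
    [&](size_t a, size_t b) { return pt[a] < pt[b]; });

  NumericVector ot(n);
  IntegerVector och(n), oex(n), ost(n), oda(n), oaa(n);
  for (size_t i = 0; i < n; ++i) {
    ot[i] = pt[idx[i]]; och[i] = pch[idx[i]]; oex[i] = pex[idx[i]];
    ost[i] = pst[idx[i]]; oda[i] = pda[idx[i]]; oaa[i] = paa[idx[i]];
  }
  return List::create(_["t"] = ot, _["channel"] = och, _["excitation"] = oex,
    _["state"] = ost, _["donor_alive"] = oda, _["acceptor_alive"] = oaa);
}

// Brownian path on a fixed grid (positions after each step), periodic box.
// [[Rcpp::export]]
NumericMatrix cpp_brownian_path(int nSteps, double dt, double D,
    double boxHalf, NumericVector pos0) {
  NumericMatrix out(nSteps + 1, 3);
  double p[3] = { pos0[0], pos0[1], pos0[2] };
  out(0, 0) = p[0]; out(0, 1) = p[1]; out(0, 2) = p[2];
  double sdStep = std::sqrt(2.0 * D * dt), span = 2.0 * boxHalf;
  for (int i = 1; i <= nSteps; ++i) {
    for (int a = 0; a < 3; ++a) {
      p[a] += norm_rand() * sdStep;
      if (R_FINITE(boxHalf)) {
        if (p[a] >  boxHalf) p[a] -= span * std::ceil((p[a] - boxHalf) / span);
        if (p[a] < -boxHalf) p[a] += span * std::ceil((-boxHalf - p[a]) / span);
      }
      out(i, a) = p[a];
    }
  }
  return out;
}
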