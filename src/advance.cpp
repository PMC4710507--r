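#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of the go-or-grow growth/invasion system on a
// masked grid: reaction terms plus first-order upwind advection (hypoxia-
// driven transport of I up the brain gradient) and a 5-point Laplacian
// (concentration-driven diffusion of I), with no-flux faces at the mask
// boundary.  Diffusion support collapses (D_eff = core_D) where >= 80% of
// the brain is dead, so invasive cells do not diffuse back into the
// necrotic core.
//
// Fields are updated in place on local copies over `nsteps` steps of size
// `dt`; negative values are clipped to zero and the clipped mass totalled.
// [[Rcpp::export]]
List advance_cpp(NumericMatrix P0, NumericMatrix I0, NumericMatrix B0state,
                 NumericMatrix N0, LogicalMatrix mask, NumericMatrix D,
                 NumericMatrix B0, NumericMatrix tau,
                 double h, double dt, int nsteps,
                 double alpha, double beta, double gamma_,
                 double delta, double eta, double Omega, double sigma,
                 double Phi, double steep, double allee, bool drive_total,
                 bool natural_log, double core_frac, double core_D) {
  const int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix P = clone(P0), I = clone(I0), B = clone(B0state), N = clone(N0);

  // masked voxels and interior faces (both end voxels in the mask)
  std::vector<int> vox;
  std::vector<int> fa, fb;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int v = r + c * nr;
      vox.push_back(v);
      if (r + 1 < nr && mask(r + 1, c)) { fa.push_back(v); fb.push_back(v + 1); }
      if (c + 1 < nc && mask(r, c + 1)) { fa.push_back(v); fb.push_back(v + nr); }
    }
  const int nv = (int)vox.size(), nf = (int)fa.size();

  const double *dD = D.begin(), *dB0 = B0.begin(), *dtau = tau.begin();
  double *pP = P.begin(), *pI = I.begin(), *pB = B.begin(), *pN = N.begin();
  std::vector<double> dImot(nr * nc, 0.0);
  const double inv_h = 1.0 / h, inv_h2 = 1.0 / (h * h);
  const double log_scale = natural_log ? 1.0 : 1.0 / std::log(10.0);
  double clipped = 0.0;

  for (int s = 0; s < nsteps; ++s) {
    // motility fluxes on interior faces
    if (delta > 0.0 || eta > 0.0) {
      for (int f = 0; f < nf; ++f) {
        const int v = fa[f], w = fb[f];
        const double Dv = (pB[v] <= core_frac * dB0[v]) ? core_D : dD[v];
        const double Dw = (pB[w] <= core_frac * dB0[w]) ? core_D : dD[w];
        double flux = delta * 0.5 * (Dv + Dw) * (pI[w] - pI[v]) * inv_h2;
        const double u = eta * (pB[w] - pB[v]) * inv_h;   // velocity toward w if > 0
        flux -= u * (u > 0.0 ? pI[v] : pI[w]) * inv_h;    // donor-cell upwinding
        dImot[v] += flux;
        dImot[w] -= flux;
      }
    }
    // pointwise reactions + Euler update
    for (int k = 0; k < nv; ++k) {
      const int v = vox[k];
      const double Pv = pP[v], Iv = pI[v], Bv = pB[v], Nv = pN[v];
      const double C = Pv + Iv + Bv + Nv;
      const double T = Pv + Iv;
      const double Chyp = sigma * std::log1p(drive_total ? T : Pv) * log_scale + Omega;
      const double H = 0.5 * (1.0 - std::tanh(steep * (Chyp - C)));
      const double eff = (allee > 0.0) ? T / (T + allee) : 1.0;
      const double M = dtau[v] * (1.0 - H) * eff;
      const double gF = gamma_ * ((Pv + Iv) / 100.0 + 1.0 / (Bv + 0.01)) *
                        0.5 * (1.0 - std::tanh(steep * (Chyp + Phi - C)));
      const double convPI = alpha * H * Pv;
      const double convIP = beta * (1.0 - H) * Iv;
      double nP = Pv + dt * (M * Pv - convPI + convIP - gF * Pv);
      double nI = Iv + dt * (convPI - convIP - gF * Iv + dImot[v]);
      double nB = Bv + dt * (-gF * Bv);
      double nN = Nv + dt * (gF * (Pv + Iv + Bv));
      if (nP < 0.0) { clipped -= nP; nP = 0.0; }
      if (nI < 0.0) { clipped -= nI; nI = 0.0; }
      if (nB < 0.0) { clipped -= nB; nB = 0.0; }
      pP[v] = nP; pI[v] = nI; pB[v] = nB; pN[v] = nN;
      dImot[v] = 0.0;
    }
  }

  return List::create(_["P"] = P, _["I"] = I, _["B"] = B, _["N"] = N,
                      _["clipped"] = clipped);
}
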