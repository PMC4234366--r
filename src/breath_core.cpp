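#include <Rcpp.h>
using namespace Rcpp;

// Within-breath solver for the airway RC network.
//
// The tree is a complete binary tree in breadth-first layout (0-based here):
// node j has children 2j+1, 2j+2; the last nt = 2^G nodes are terminal
// airways, each ending in an elastic unit of compliance C. Radii (hence
// resistances) are constant within the breath. Each 10 ms step is a backward
// Euler update solved exactly: every subtree is collapsed bottom-up to a
// Thevenin form P = a + b q (b depends only on resistances and dt/C, so it
// is computed once per breath), the boundary condition is applied at the
// root (prescribed constant inspiratory flow, or airway-opening pressure
// clamped to PEEP during passive expiration), and flows/pressures are
// distributed top-down. Unit volumes are in mL above the relaxation volume
// at PEEP; pressures are in cmH2O relative to PEEP.
//
// The transmural pressure of airway j at each step is
//   Ptm_j = P_lumen,mid + Pel0 + Pel(t) + tau * Pel_tidal(t) * (lambda_j - 1)
// where Pel(t) is the mean elastic recoil above PEEP and the last term is
// parenchymal distortion: lambda_j is the tidal expansion of j's subtree
// relative to the tree mean, with expansion measured within the breath
// (volume above the start-of-breath volume). Writing Pel_tidal =
// dVbar/C the distortion term reduces to tau * (dVbar_sub - dVbar)/C,
// which is well-defined even at zero mean expansion. A subtree that does
// not ventilate loses up to tau * Pel_tidal of outward traction at peak
// inflation; an over-expanding subtree gains it. The per-breath maximum of
// Ptm_j is returned.
//
// [[Rcpp::export]]
List breath_core(int G, NumericVector Rres, double C_unit, double dt,
                 int n_insp, int n_exp, double Q_insp,
                 double tau, double Pel0,
                 NumericVector V_start, double peep,
                 IntegerVector trace_ids) {
  const int n = (1 << (G + 1)) - 1;
  const int nt = 1 << G;
  const int term0 = nt - 1;  // first terminal node
  if (Rres.size() != n) stop("resistance vector length mismatch");
  if (V_start.size() != nt) stop("unit volume vector length mismatch");

  std::vector<double> b_in(n), a_in(n), q(n), Ptop(n), Pbot(n);
  std::vector<double> S(n);       // subtree unit-volume sums
  std::vector<double> V(V_start.begin(), V_start.end());
  NumericVector ptm_peak(n, R_NegInf);
  const int n_steps = n_insp + n_exp;
  NumericVector inlet(n_steps);
  NumericVector vent(nt);

  // Thevenin slopes, fixed for the breath
  for (int j = n - 1; j >= 0; --j) {
    if (j >= term0) {
      b_in[j] = dt / C_unit + Rres[j];
    } else {
      double b1 = b_in[2 * j + 1], b2 = b_in[2 * j + 2];
      b_in[j] = b1 * b2 / (b1 + b2) + Rres[j];
    }
  }

  std::vector<double> cnt(n);  // terminal units under each node
  for (int j = n - 1; j >= 0; --j)
    cnt[j] = (j >= term0) ? 1.0 : cnt[2 * j + 1] + cnt[2 * j + 2];

  NumericVector V_end_insp(nt);
  const int n_tr = trace_ids.size();
  NumericMatrix ptm_trace(n_tr > 0 ? n_steps : 0, n_tr);

  for (int s = 0; s < n_steps; ++s) {
    // bottom-up offsets
    for (int j = n - 1; j >= 0; --j) {
      if (j >= term0) {
        a_in[j] = V[j - term0] / C_unit;
      } else {
        int c1 = 2 * j + 1, c2 = 2 * j + 2;
        double b1 = b_in[c1], b2 = b_in[c2];
        a_in[j] = (a_in[c1] * b2 + a_in[c2] * b1) / (b1 + b2);
      }
    }
    // root boundary condition
    if (s < n_insp) {
      q[0] = Q_insp;
      Ptop[0] = a_in[0] + b_in[0] * q[0];
    } else {
      Ptop[0] = 0.0;
      q[0] = -a_in[0] / b_in[0];
    }
    // top-down distribution and volume update
    for (int j = 0; j < n; ++j) {
      Pbot[j] = Ptop[j] - Rres[j] * q[j];
      if (j >= term0) {
        V[j - term0] += q[j] * dt;
      } else {
        int c1 = 2 * j + 1, c2 = 2 * j + 2;
        Ptop[c1] = Pbot[j];
        Ptop[c2] = Pbot[j];
        q[c1] = (Pbot[j] - a_in[c1]) / b_in[c1];
        q[c2] = (Pbot[j] - a_in[c2]) / b_in[c2];
      }
    }
    inlet[s] = peep + Ptop[0];
    // recoil and tethering state after the update; S holds within-breath
    // expansion sums (volume above the start-of-breath state)
    for (int j = n - 1; j >= 0; --j)
      S[j] = (j >= term0) ? V[j - term0] - V_start[j - term0]
                          : S[2 * j + 1] + S[2 * j + 2];
    double Vbar_abs = 0.0;
    for (int i = 0; i < nt; ++i) Vbar_abs += V[i];
    Vbar_abs /= nt;
    double Pel = Vbar_abs / C_unit;
    double dVbar = S[0] / nt;
    for (int j = 0; j < n; ++j) {
      double tether = tau * (S[j] / cnt[j] - dVbar) / C_unit;
      double p_mid = 0.5 * (Ptop[j] + Pbot[j]);
      double ptm = p_mid + Pel0 + Pel + tether;
      if (ptm > ptm_peak[j]) ptm_peak[j] = ptm;
    }
    for (int t = 0; t < n_tr; ++t) {
      int j = trace_ids[t];
      double tether = tau * (S[j] / cnt[j] - dVbar) / C_unit;
      ptm_trace(s, t) = 0.5 * (Ptop[j] + Pbot[j]) + Pel0 + Pel + tether;
    }
    if (s == n_insp - 1)
      for (int i = 0; i < nt; ++i) V_end_insp[i] = V[i];
  }
  for (int i = 0; i < nt; ++i) vent[i] = V_end_insp[i] - V_start[i];

  return List::create(_["ventilation"] = vent,
                      _["ptm_peak"] = ptm_peak,
                      _["inlet_pressure"] = inlet,
                      _["V_end"] = NumericVector(V.begin(), V.end()),
                      _["total_inspired"] = Q_insp * dt * n_insp,
                      _["ptm_trace"] = ptm_trace);
}
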