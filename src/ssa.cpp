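#include <Rcpp.h>
using namespace Rcpp;

// Exact (Gillespie) simulation of the two-state gene expression model.
//
// Six events per allele with propensities
//   activation    kon  * (nG_total - nG_on)
//   inactivation  koff * nG_on
//   transcription Sm   * nG_on
//   mRNA decay    Dm   * nM
//   translation   Sp   * nM
//   protein decay Dp   * nP
//
// Event selection uses cumulative-propensity inversion with the fixed
// ordering above; the ordering is part of the reproducibility contract.
// All randomness comes from R's RNG so set.seed() governs trajectories.

static inline int pick_event(const double *a, int n, double rtot) {
  double u = unif_rand() * rtot;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += a[i];
    if (u <= acc) return i;
  }
  return n - 1; // guard against floating-point underrun
}

// [[Rcpp::export]]
List ssa_allele_cpp(double kon, double koff, double Sm, double Sp,
                    double Dm, double Dp, int nG_total, double t_end,
                    bool promoter_on, bool record) {
  RNGScope scope;
  int nG = promoter_on ? nG_total : 0;
  double nM = 0.0, nP = 0.0, t = 0.0;
  double a[6];

  std::vector<double> traj;
  if (record) {
    traj.push_back(t); traj.push_back(nG);
    traj.push_back(nM); traj.push_back(nP);
  }

  for (;;) {
    a[0] = kon * (nG_total - nG);
    a[1] = koff * nG;
    a[2] = Sm * nG;
    a[3] = Dm * nM;
    a[4] = Sp * nM;
    a[5] = Dp * nP;
    double rtot = a[0] + a[1] + a[2] + a[3] + a[4] + a[5];
    if (rtot <= 0.0) { t = t_end; break; }
    double tau = exp_rand() / rtot;
    if (t + tau > t_end) { t = t_end; break; }
    t += tau;
    switch (pick_event(a, 6, rtot)) {
      case 0: nG += 1; break;
      case 1: nG -= 1; break;
      case 2: nM += 1; break;
      case 3: nM -= 1; break;
      case 4: nP += 1; break;
      case 5: nP -= 1; break;
    }
    if (record) {
      traj.push_back(t); traj.push_back(nG);
      traj.push_back(nM); traj.push_back(nP);
    }
  }

  List out = List::create(_["nG_on"] = nG, _["nM"] = nM, _["nP"] = nP,
                          _["t"] = t_end);
  if (record) {
    int nrow = traj.size() / 4;
    NumericMatrix m(nrow, 4);
    for (int i = 0; i < nrow; ++i)
      for (int j = 0; j < 4; ++j) m(i, j) = traj[4 * i + j];
    colnames(m) = CharacterVector::create("t", "nG_on", "nM", "nP");
    out["trajectory"] = m;
  }
  return out;
}

// Batch of independent alleles; returns an n x 2 matrix (nM, nP) of
// end-point counts.
// [[Rcpp::export]]
NumericMatrix ssa_batch_cpp(double kon, double koff, double Sm, double Sp,
                            double Dm, double Dp, int nG_total, double t_end,
                            bool promoter_on, int n) {
  RNGScope scope;
  NumericMatrix out(n, 2);
  double a[6];
  for (int k = 0; k < n; ++k) {
    int nG = promoter_on ? nG_total : 0;
    double nM = 0.0, nP = 0.0, t = 0.0;
    for (;;) {
      a[0] = kon * (nG_total - nG);
      a[1] = koff * nG;
      a[2] = Sm * nG;
      a[3] = Dm * nM;
      a[4] = Sp * nM;
      a[5] = Dp * nP;
      double rtot = a[0] + a[1] + a[2] + a[3] + a[4] + a[5];
      if (rtot <= 0.0) break;
      double tau = exp_rand() / rtot;
      if (t + tau > t_end) break;
      t += tau;
      switch (pick_event(a, 6, rtot)) {
        case 0: nG += 1; break;
        case 1: nG -= 1; break;
        case 2: nM += 1; break;
        case 3: nM -= 1; break;
        case 4: nP += 1; break;
        case 5: nP -= 1; break;
      }
    }
    out(k, 0) = nM;
    out(k, 1) = nP;
  }
  colnames(out) = CharacterVector::create("nM", "nP");
  return out;
}

// Coupled allele pair sharing one Markov clock (12 propensities).
// While any gene copy of one allele is 'on', the partner allele's
// activation rate is reduced to kon * (1 - phi) (mutual trans-inhibition).
// phi = 0 reduces exactly to two independent alleles.
// Returns an n x 4 matrix (mrna_a, protein_a, mrna_b, protein_b);
// final promoter states are returned alongside for diagnostics.
// [[Rcpp::export]]
List ssa_pair_coupled_cpp(double kon, double koff, double Sm, double Sp,
                          double Dm, double Dp, int nG_total, double phi,
                          double t_end, bool promoter_on, int n) {
  RNGScope scope;
  NumericMatrix out(n, 4);
  IntegerMatrix gstate(n, 2);
  double a[12];
  for (int k = 0; k < n; ++k) {
    int nG[2] = {promoter_on ? nG_total : 0, promoter_on ? nG_total : 0};
    double nM[2] = {0.0, 0.0}, nP[2] = {0.0, 0.0};
    double t = 0.0;
    for (;;) {
      for (int i = 0; i < 2; ++i) {
        int j = 1 - i;
        double kon_i = (nG[j] > 0) ? kon * (1.0 - phi) : kon;
        a[6 * i + 0] = kon_i * (nG_total - nG[i]);
        a[6 * i + 1] = koff * nG[i];
        a[6 * i + 2] = Sm * nG[i];
        a[6 * i + 3] = Dm * nM[i];
        a[6 * i + 4] = Sp * nM[i];
        a[6 * i + 5] = Dp * nP[i];
      }
      double rtot = 0.0;
      for (int e = 0; e < 12; ++e) rtot += a[e];
      if (rtot <= 0.0) break;
      double tau = exp_rand() / rtot;
      if (t + tau > t_end) break;
      t += tau;
      int ev = pick_event(a, 12, rtot);
      int i = ev / 6;
      switch (ev % 6) {
        case 0: nG[i] += 1; break;
        case 1: nG[i] -= 1; break;
        case 2: nM[i] += 1; break;
        case 3: nM[i] -= 1; break;
        case 4: nP[i] += 1; break;
        case 5: nP[i] -= 1; break;
      }
    }
    out(k, 0) = nM[0]; out(k, 1) = nP[0];
    out(k, 2) = nM[1]; out(k, 3) = nP[1];
    gstate(k, 0) = nG[0]; gstate(k, 1) = nG[1];
  }
  colnames(out) =
      CharacterVector::create("mrna_a", "protein_a", "mrna_b", "protein_b");
  return List::create(_["counts"] = out, _["promoter_on"] = gstate);
}
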