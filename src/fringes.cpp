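#include <Rcpp.h>
using namespace Rcpp;

// Accumulate the raw interferogram of one A-line from a set of discrete
// sub-resolution scatterers.
//
// Each scatterer s at optical depth z_s contributes
//   a_s * exp(-sum_l mu[k, l] * path[s, l]) * cos(2 * k * z_s + phi_s)
// at every wavenumber sample k. mu holds the per-layer intensity attenuation
// coefficient evaluated on the k grid (units 1/um); path holds the one-way
// geometric path of scatterer s through layer l (um), so the exponent is the
// one-way optical depth and the squared field carries the roundtrip factor
// exp(-2 * sum mu * path) of the Beer-Lambert law.
//
// k: n_k wavenumber samples (rad/um)
// z: n_s scatterer depths (um)
// amp: n_s scatterer amplitudes
// phase: n_s extra phases (rad); 0 for the co-polarized channel
// mu: n_k x L per-layer attenuation on the k grid
// path: n_s x L one-way path lengths
// [[Rcpp::export]]
NumericVector fringe_accumulate(NumericVector k, NumericVector z,
                                NumericVector amp, NumericVector phase,
                                NumericMatrix mu, NumericMatrix path) {
  const int nk = k.size();
  const int ns = z.size();
  const int nl = mu.ncol();
  if (amp.size() != ns || phase.size() != ns || path.nrow() != ns ||
      mu.nrow() != nk || path.ncol() != nl)
    stop("inconsistent scatterer/grid dimensions");
  NumericVector out(nk);
  std::vector<double> att(nk);
  for (int s = 0; s < ns; ++s) {
    for (int i = 0; i < nk; ++i) att[i] = 0.0;
    for (int l = 0; l < nl; ++l) {
      const double p = path(s, l);
      if (p == 0.0) continue;
      for (int i = 0; i < nk; ++i) att[i] += mu(i, l) * p;
    }
    const double zs2 = 2.0 * z[s];
    const double ph = phase[s];
    const double a = amp[s];
    for (int i = 0; i < nk; ++i)
      out[i] += a * std::exp(-att[i]) * std::cos(zs2 * k[i] + ph);
  }
  return out;
}

// Whole-volume variant: scatterers of all A-lines are concatenated; A-line a
// (0-based) owns scatterers [start[a], start[a + 1]). Returns n_k x n_alines.
// [[Rcpp::export]]
NumericMatrix fringe_accumulate_volume(NumericVector k, NumericVector z,
                                       NumericVector amp, NumericVector phase,
                                       NumericMatrix mu, NumericMatrix path,
                                       IntegerVector start) {
  const int nk = k.size();
  const int ns = z.size();
  const int nl = mu.ncol();
  const int na = start.size() - 1;
  if (amp.size() != ns || phase.size() != ns || path.nrow() != ns ||
      mu.nrow() != nk || path.ncol() != nl || start[na] != ns)
    stop("inconsistent scatterer/grid dimensions");
  NumericMatrix out(nk, na);
  std::vector<double> att(nk);
  for (int a = 0; a < na; ++a) {
    double *col = &out(0, a);
    for (int s = start[a]; s < start[a + 1]; ++s) {
      for (int i = 0; i < nk; ++i) att[i] = 0.0;
      for (int l = 0; l < nl; ++l) {
        const double p = path(s, l);
        if (p == 0.0) continue;
        for (int i = 0; i < nk; ++i) att[i] += mu(i, l) * p;
      }
      const double zs2 = 2.0 * z[s];
      const double ph = phase[s];
      const double am = amp[s];
      for (int i = 0; i < nk; ++i)
        col[i] += am * std::exp(-att[i]) * std::cos(zs2 * k[i] + ph);
    }
  }
  return out;
}
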