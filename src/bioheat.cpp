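#include <Rcpp.h>
using namespace Rcpp;

// Explicit finite-volume update of the axisymmetric heat equation
//   rho c dT/dt = (1/r) d/dr (r k dT/dr) + d/dz (k dT/dz) + q
// on a cell-centred (r, z) grid.  Face conductances (W/K) are precomputed in
// R; faces on the outer radius and distal z connect to the Dirichlet bath,
// faces with zero conductance (axis, transducer face) are insulated.
//
// T, heatW, invC: nr x nz (heatW = q*V in W, invC = 1/(rho c V) in K/J).
// Gr: (nr+1) x nz radial face conductances; Gr(i, j) is the face between
//     cells (i-1, j) and (i, j), Gr(nr, j) the outer face to the bath.
// Gz: nr x (nz+1) axial face conductances; Gz(i, j) between cells (i, j-1)
//     and (i, j), Gz(i, nz) the distal face to the bath.
//
// Probe readings are linear combinations of cell temperatures: probe p uses
// entries probe_off[p] .. probe_off[p+1]-1 of (probe_i, probe_w), with
// probe_i a 0-based linear index into T.

// [[Rcpp::export]]
List bioheat_run(NumericMatrix T0, NumericMatrix heatW, NumericMatrix invC,
                 NumericMatrix Gr, NumericMatrix Gz, double bath, double dt,
                 int n_steps, int sample_stride, IntegerVector probe_i,
                 NumericVector probe_w, IntegerVector probe_off) {
  const int nr = T0.nrow(), nz = T0.ncol();
  const int np = probe_off.size() - 1;
  std::vector<double> a(T0.begin(), T0.end());
  std::vector<double> b(a);

  const int n_samples = (sample_stride > 0) ? (n_steps / sample_stride + 1) : 1;
  NumericMatrix series(n_samples, np);
  NumericVector times(n_samples);

  auto record = [&](int row, double t, const std::vector<double>& cur) {
    times[row] = t;
    for (int p = 0; p < np; ++p) {
      double acc = 0.0;
      for (int k = probe_off[p]; k < probe_off[p + 1]; ++k)
        acc += probe_w[k] * cur[probe_i[k]];
      series(row, p) = acc;
    }
  };

  record(0, 0.0, a);
  int row = 1;

  for (int step = 1; step <= n_steps; ++step) {
    for (int j = 0; j < nz; ++j) {
      const int col = j * nr;
      for (int i = 0; i < nr; ++i) {
        const double t = a[col + i];
        double flux = 0.0;
        const double gin = Gr(i, j);
        if (gin > 0.0) flux += gin * (a[col + i - 1] - t);
        const double gout = Gr(i + 1, j);
        if (gout > 0.0)
          flux += gout * (((i + 1 < nr) ? a[col + i + 1] : bath) - t);
        const double gup = Gz(i, j);
        if (gup > 0.0) flux += gup * (a[col - nr + i] - t);
        const double gdn = Gz(i, j + 1);
        if (gdn > 0.0)
          flux += gdn * (((j + 1 < nz) ? a[col + nr + i] : bath) - t);
        b[col + i] = t + dt * invC(i, j) * (flux + heatW(i, j));
      }
    }
    a.swap(b);
    if (sample_stride > 0 && step % sample_stride == 0 && row < n_samples) {
      record(row, step * dt, a);
      ++row;
    }
  }

  NumericMatrix Tend(nr, nz);
  std::copy(a.begin(), a.end(), Tend.begin());
  return List::create(_["T"] = Tend, _["series"] = series, _["times"] = times);
}
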