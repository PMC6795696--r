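#include <Rcpp.h>
using namespace Rcpp;

// Iterated conditional modes on a Potts-prior MRF.
//
// nlp   : nx*ny*nz*K column-major array of -log(max(p, eps)) data costs
// init  : nx*ny*nz initial label indices in 1..K (0 = not scored)
// valid : nx*ny*nz flags for scored voxels
// neigh : 0 = 8-connected within axial slice, 1 = 6-connected in 3-D
//
// Voxels are updated sequentially in raster (column-major) order; each
// update minimizes the local energy, with ties broken toward the lowest
// label index, so the global energy is non-increasing sweep over sweep.

// [[Rcpp::export(name = ".icm_sweeps")]]
List icm_sweeps(NumericVector nlp, IntegerVector init, LogicalVector valid,
                IntegerVector dims, double beta, int neigh, int max_iter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], K = dims[3];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (init.size() != nvox || valid.size() != nvox ||
      nlp.size() != nvox * K)
    stop("dimension mismatch in icm_sweeps");

  IntegerVector lab = clone(init);
  std::vector<int> dx, dy, dz;
  if (neigh == 0) {            // 2D-8: all in-slice offsets
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        if (a != 0 || b != 0) { dx.push_back(a); dy.push_back(b); dz.push_back(0); }
  } else {                     // 3D-6: face neighbors
    int ax[6] = {1, -1, 0, 0, 0, 0};
    int ay[6] = {0, 0, 1, -1, 0, 0};
    int az[6] = {0, 0, 0, 0, 1, -1};
    for (int i = 0; i < 6; ++i) { dx.push_back(ax[i]); dy.push_back(ay[i]); dz.push_back(az[i]); }
  }
  const int nn = dx.size();

  std::vector<int> trace;
  bool converged = false;
  for (int it = 0; it < max_iter; ++it) {
    int changes = 0;
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          const R_xlen_t v = (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          if (!valid[v]) continue;
          // count valid neighbors holding each label
          int nbr_count[64];
          for (int k = 0; k < K; ++k) nbr_count[k] = 0;
          int nbr_total = 0;
          for (int m = 0; m < nn; ++m) {
            const int xx = x + dx[m], yy = y + dy[m], zz = z + dz[m];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            const R_xlen_t u = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (!valid[u]) continue;
            ++nbr_count[lab[u] - 1];
            ++nbr_total;
          }
          int best = 0;
          double best_e = R_PosInf;
          for (int k = 0; k < K; ++k) {
            const double e = nlp[v + nvox * k] +
              beta * (nbr_total - nbr_count[k]);
            if (e < best_e) { best_e = e; best = k; }
          }
          if (best + 1 != lab[v]) { lab[v] = best + 1; ++changes; }
        }
      }
    }
    trace.push_back(changes);
    if (changes == 0) { converged = true; break; }
  }
  return List::create(_["labels"] = lab,
                      _["trace"] = wrap(trace),
                      _["converged"] = converged);
}
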