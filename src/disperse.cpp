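#include <Rcpp.h>
using namespace Rcpp;

// Wind dispersal of seeds over the patch grid.
//
// Each seed starts at continuous position (x0, y0) in patch units, draws a
// uniform direction, and advances one patch length per substep for up to
// `maxPatches` substeps. Entering a patch covered by at least one crown
// triggers a capture attempt with probability `capture`. Seeds leaving the
// (absorbing) landscape or finishing their flight unattached are lost.
// With maxPatches == 0 the capture attempt happens at the origin patch.
//
// Returns, per seed, the 0-based linear landing patch index
// (px * ny + py) or -1 if lost. Uses R's RNG so runs are reproducible
// under set.seed().
// [[Rcpp::export(name = ".disperseSeeds")]]
IntegerVector disperseSeeds(NumericVector x0, NumericVector y0,
                            int maxPatches, IntegerMatrix canopy,
                            double capture) {
  const int n = x0.size();
  const int ny = canopy.nrow(), nx = canopy.ncol();
  IntegerVector out(n, -1);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double x = x0[i], y = y0[i];
    const double theta = unif_rand() * 2.0 * M_PI;
    const double dx = std::cos(theta), dy = std::sin(theta);
    int px = (int)std::floor(x), py = (int)std::floor(y);
    if (maxPatches == 0) {
      if (px >= 0 && px < nx && py >= 0 && py < ny &&
          canopy(py, px) > 0 && unif_rand() < capture)
        out[i] = px * ny + py;
      continue;
    }
    int prevPx = px, prevPy = py;
    for (int s = 0; s < maxPatches; ++s) {
      x += dx; y += dy;
      px = (int)std::floor(x); py = (int)std::floor(y);
      if (px < 0 || px >= nx || py < 0 || py >= ny) break; // lost outside
      if (px == prevPx && py == prevPy) continue;
      prevPx = px; prevPy = py;
      if (canopy(py, px) > 0 && unif_rand() < capture) {
        out[i] = px * ny + py;
        break;
      }
    }
  }
  return out;
}
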