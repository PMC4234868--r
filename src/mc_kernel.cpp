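#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Weighted photon-packet transport in a laterally infinite layered slab with
// matched refractive indices and absorbing (Dirichlet) outer boundaries.
// z increases downward (cm). The dual-fiber probe tip plane at z = probeDepth
// acts as the absorbing top surface of the medium ahead of the probe: a
// packet crossing it moving upward (-z) is collected if inside the
// detector-fiber disc with |cos| >= cosMin, otherwise absorbed by the probe
// face (counted as escaped).
//
// The random stream is a 48-bit LCG (rand48 constants) so the scalar R
// reference tracer in the test suite can consume an identical stream; every
// floating-point expression here is mirrored there.

namespace {

struct Rand48 {
  uint64_t state;
  static const uint64_t MASK = (1ULL << 48) - 1;
  void seed(double s) {
    state = ((uint64_t)s * 65536ULL + 13070ULL) & MASK;
  }
  // uniform on (0, 1]
  double next() {
    state = (25214903917ULL * state + 11ULL) & MASK;
    return ((double)state + 1.0) / 281474976710656.0;
  }
};

// Henyey-Greenstein deflection + uniform azimuth, MCML-style direction update.
inline void hgScatter(double g, double u1, double u2,
                      double &ux, double &uy, double &uz) {
  double ct;
  if (g == 0.0) {
    ct = 2.0 * u1 - 1.0;
  } else {
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u1);
    ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  }
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  double st = sqrt(1.0 - ct * ct);
  double phi = 2.0 * M_PI * u2;
  double cp = cos(phi);
  double sp = sin(phi);
  double nux, nuy, nuz;
  if (fabs(uz) > 0.99999) {
    nux = st * cp;
    nuy = st * sp;
    nuz = (uz >= 0.0) ? ct : -ct;
  } else {
    double den = sqrt(1.0 - uz * uz);
    nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    nuz = -den * st * cp + uz * ct;
  }
  ux = nux;
  uy = nuy;
  uz = nuz;
}

} // namespace

// [[Rcpp::export(name = ".mcTracePhotonsCpp")]]
List mcTracePhotonsCpp(NumericVector muA, NumericVector muS, NumericVector g,
                       NumericVector thicknessCm, double probeDepthCm,
                       double detOffsetCm, double detRadiusCm, double cosMin,
                       int nPhotons, double seed, double rouletteWmin,
                       double roulettePsurv, bool perPhoton) {
  const int L = muA.size();
  std::vector<double> zb(L + 1), mt(L), invMt(L), absFrac(L);
  zb[0] = 0.0;
  for (int i = 0; i < L; ++i) {
    zb[i + 1] = zb[i] + thicknessCm[i];
    mt[i] = muA[i] + muS[i];
    invMt[i] = 1.0 / mt[i];
    absFrac[i] = muA[i] / mt[i];
  }
  const double z0 = probeDepthCm;
  const double detr2 = detRadiusCm * detRadiusCm;

  Rand48 rng;
  rng.seed(seed);

  NumericVector pdet, pesc, pabs, prou;
  if (perPhoton) {
    pdet = NumericVector(nPhotons);
    pesc = NumericVector(nPhotons);
    pabs = NumericVector(nPhotons);
    prou = NumericVector(nPhotons);
  }

  double sumDet = 0.0, sumDetSq = 0.0;
  const long long maxEvents = 100000000LL;

  for (int p = 0; p < nPhotons; ++p) {
    double x = 0.0, y = 0.0, z = z0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    int cur = 0;
    while (cur < L - 1 && z0 >= zb[cur + 1]) ++cur;
    double det = 0.0, esc = 0.0, absb = 0.0, roul = 0.0;
    bool alive = true;
    long long events = 0;

    while (alive) {
      double srem = -log(rng.next());
      bool interact = false;
      // propagate, splitting the dimensionless step at planes
      while (true) {
        if (++events > maxEvents) { absb += w; alive = false; break; }
        double mut = mt[cur];
        double d = srem * invMt[cur];
        double znew = z + d * uz;
        if (uz > 0.0) {
          if (znew < zb[cur + 1]) {  // interaction before the layer bottom
            x += d * ux;
            y += d * uy;
            z = znew;
            interact = true;
            break;
          }
          double tb = (zb[cur + 1] - z) / uz;
          x += tb * ux;
          y += tb * uy;
          srem -= tb * mut;
          z = zb[cur + 1];
          if (cur == L - 1) { esc = w; alive = false; break; }
          ++cur;
          continue;
        }
        if (uz < 0.0) {
          // binding upward plane: probe tip plane if it lies at/above the
          // current layer top, else the layer top
          double zlim = (z0 >= zb[cur]) ? z0 : zb[cur];
          if (znew > zlim) {  // interaction before any plane
            x += d * ux;
            y += d * uy;
            z = znew;
            interact = true;
            break;
          }
          double tb = (zlim - z) / uz;
          x += tb * ux;
          y += tb * uy;
          srem -= tb * mut;
          z = zlim;
          if (zlim == z0) {
            // probe tip plane: collect or absorb on the probe face
            double dx = x - detOffsetCm;
            double r2 = dx * dx + y * y;
            if (r2 <= detr2 && -uz >= cosMin) det = w; else esc = w;
            alive = false;
            break;
          }
          if (cur == 0) { esc = w; alive = false; break; }
          --cur;
          continue;
        }
        // uz == 0: interaction in-plane
        x += d * ux;
        y += d * uy;
        interact = true;
        break;
      }
      if (!alive || !interact) continue;
      // interaction: deposit absorbed weight, roulette, scatter
      double aw = w * absFrac[cur];
      absb += aw;
      w -= aw;
      if (w < rouletteWmin) {
        double u = rng.next();
        if (u <= roulettePsurv) {
          roul -= w * 9.0;
          w *= 10.0;
        } else {
          roul += w;
          alive = false;
          continue;
        }
      }
      double u1 = rng.next();
      double u2 = rng.next();
      hgScatter(g[cur], u1, u2, ux, uy, uz);
    }

    sumDet += det;
    sumDetSq += det * det;
    if (perPhoton) {
      pdet[p] = det;
      pesc[p] = esc;
      pabs[p] = absb;
      prou[p] = roul;
    }
  }

  List out = List::create(
      Named("detectedSum") = sumDet,
      Named("detectedSumSq") = sumDetSq,
      Named("nPhotons") = nPhotons);
  if (perPhoton) {
    out["detected"] = pdet;
    out["escaped"] = pesc;
    out["absorbed"] = pabs;
    out["roulette"] = prou;
  }
  return out;
}
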