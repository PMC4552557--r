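#include <Rcpp.h>
using namespace Rcpp;

// State vector layout (length 3*Nr*Nz + 2*(Nz + 2*Nr)):
//   [rho_DD | rho_DT | rho_E] on the (r,z) volume grid, column index
//   idx = i + Nr*k for radial cell i (0..Nr-1) and axial cell k (0..Nz-1),
//   then [rho_d | rho_de] on the membrane patches: Nz lateral patches
//   (adjacent to the outermost radial cells), Nr patches on the z=0 cap,
//   Nr patches on the z=L cap.
//
// Rate vector k (fixed order):
//   0 k+1, 1 k-1, 2 k+2, 3 k-2, 4 k+2', 5 k-2', 6 k+3, 7 k-3,
//   8 k+4, 9 k-4, 10 D_D, 11 D_E

static inline void unpack_dims(const List& g, int& Nr, int& Nz, int& nvol,
                               int& nmem) {
  Nr = as<int>(g["Nr"]);
  Nz = as<int>(g["Nz"]);
  nvol = Nr * Nz;
  nmem = Nz + 2 * Nr;
}

// [[Rcpp::export]]
NumericVector min_rhs_cpp(NumericVector y, List g, NumericVector k) {
  int Nr, Nz, nvol, nmem;
  unpack_dims(g, Nr, Nz, nvol, nmem);
  const double dr = as<double>(g["dr"]);
  const double dz = as<double>(g["dz"]);
  const NumericVector Vr = g["Vr"];    // cell volume per radial index
  const NumericVector Ar = g["Ar"];    // radial face area between i,i+1
  const NumericVector Az = g["Az"];    // axial face area per radial index
  const NumericVector pA = g["patch_area"];      // membrane patch areas
  const IntegerVector pc = g["patch_cell0"];     // 0-based adjacent cell

  const double k1p = k[0], k1m = k[1], k2p = k[2], k2m = k[3];
  const double k2cp = k[4], k2cm = k[5], k3p = k[6], k3m = k[7];
  const double k4p = k[8], k4m = k[9], DD = k[10], DE = k[11];

  const double* yDD = y.begin();
  const double* yDT = yDD + nvol;
  const double* yE = yDT + nvol;
  const double* yd = yE + nvol;
  const double* yde = yd + nmem;

  NumericVector dy(y.size());
  double* dDD = dy.begin();
  double* dDT = dDD + nvol;
  double* dE = dDT + nvol;
  double* dd = dE + nvol;
  double* dde = dd + nmem;

  // cytoplasmic diffusion (finite volume, zero-flux outer faces; membrane
  // exchange enters as sources below)
  const double* rho[3] = {yDD, yDT, yE};
  double* drho[3] = {dDD, dDT, dE};
  const double Dco[3] = {DD, DD, DE};
  for (int s = 0; s < 3; ++s) {
    const double D = Dco[s];
    const double* r = rho[s];
    double* d = drho[s];
    for (int kz = 0; kz < Nz; ++kz) {
      const int off = Nr * kz;
      for (int i = 0; i < Nr - 1; ++i) {
        const double f = D * Ar[i] * (r[off + i + 1] - r[off + i]) / dr;
        d[off + i] += f / Vr[i];
        d[off + i + 1] -= f / Vr[i + 1];
      }
    }
    for (int kz = 0; kz < Nz - 1; ++kz) {
      for (int i = 0; i < Nr; ++i) {
        const int a = i + Nr * kz, b = a + Nr;
        const double f = D * Az[i] * (r[b] - r[a]) / dz;
        d[a] += f / Vr[i];
        d[b] -= f / Vr[i];
      }
    }
  }

  // volumetric nucleotide exchange
  for (int c = 0; c < nvol; ++c) {
    const double j1 = k1p * yDD[c] - k1m * yDT[c];
    dDD[c] -= j1;
    dDT[c] += j1;
  }

  // membrane reactions + boundary exchange with the adjacent volume cell
  for (int m = 0; m < nmem; ++m) {
    const int c = pc[m];
    const int ir = c % Nr;
    const double AoV = pA[m] / Vr[ir];
    const double dsum = yd[m] + yde[m];
    const double j2 = k2p * yDT[c] - k2m * yd[m];
    const double j2c = k2cp * yDT[c] * dsum - k2cm * yd[m] * dsum;
    const double j3 = k3p * yE[c] * yd[m] - k3m * yde[m];
    const double j4 = k4p * yde[m] - k4m * yDD[c] * yE[c];
    dd[m] += j2 + j2c - j3;
    dde[m] += j3 - j4;
    dDD[c] += j4 * AoV;
    dDT[c] -= (j2 + j2c) * AoV;
    dE[c] += (j4 - j3) * AoV;
  }

  return dy;
}

static inline double sigma_term(double jp, double jm) {
  if (jp <= 0.0 || jm <= 0.0) {
    if (jp == 0.0 && jm == 0.0) return 0.0;
    return R_PosInf;  // irreversible limit: divergent dissipation
  }
  return (jp - jm) * std::log(jp / jm);
}

// Integrated fluxes, per-step reaction dissipation, diffusion dissipation
// and species bookkeeping for a single state snapshot.
// [[Rcpp::export]]
List min_diag_cpp(NumericVector y, List g, NumericVector k) {
  int Nr, Nz, nvol, nmem;
  unpack_dims(g, Nr, Nz, nvol, nmem);
  const double dr = as<double>(g["dr"]);
  const double dz = as<double>(g["dz"]);
  const NumericVector Vr = g["Vr"];
  const NumericVector Ar = g["Ar"];
  const NumericVector Az = g["Az"];
  const NumericVector pA = g["patch_area"];
  const IntegerVector pc = g["patch_cell0"];

  const double k1p = k[0], k1m = k[1], k2p = k[2], k2m = k[3];
  const double k2cp = k[4], k2cm = k[5], k3p = k[6], k3m = k[7];
  const double k4p = k[8], k4m = k[9], DD = k[10], DE = k[11];

  const double* yDD = y.begin();
  const double* yDT = yDD + nvol;
  const double* yE = yDT + nvol;
  const double* yd = yE + nvol;
  const double* yde = yd + nmem;

  double J1 = 0, J2 = 0, J2c = 0, J3 = 0, J4 = 0;
  double s1 = 0, s2 = 0, s3 = 0, s4 = 0;
  double cytD = 0, cytE = 0, memD = 0, memE = 0;

  for (int kz = 0; kz < Nz; ++kz) {
    for (int i = 0; i < Nr; ++i) {
      const int c = i + Nr * kz;
      const double V = Vr[i];
      const double jp = k1p * yDD[c], jm = k1m * yDT[c];
      J1 += (jp - jm) * V;
      s1 += sigma_term(jp, jm) * V;
      cytD += (yDD[c] + yDT[c]) * V;
      cytE += yE[c] * V;
    }
  }

  for (int m = 0; m < nmem; ++m) {
    const int c = pc[m];
    const double A = pA[m];
    const double dsum = yd[m] + yde[m];
    const double j2p = k2p * yDT[c], j2m = k2m * yd[m];
    const double j2cp = k2cp * yDT[c] * dsum, j2cm = k2cm * yd[m] * dsum;
    const double j3p = k3p * yE[c] * yd[m], j3m = k3m * yde[m];
    const double j4p = k4p * yde[m], j4m = k4m * yDD[c] * yE[c];
    J2 += (j2p - j2m) * A;
    J2c += (j2cp - j2cm) * A;
    J3 += (j3p - j3m) * A;
    J4 += (j4p - j4m) * A;
    // spontaneous and cooperative attachment share one free-energy drop:
    // sigma_2 = (j2 + j2') ln(j+2/j-2)
    if (j2p > 0.0 && j2m > 0.0) {
      s2 += ((j2p - j2m) + (j2cp - j2cm)) * std::log(j2p / j2m) * A;
    } else if (!(j2p == 0.0 && j2m == 0.0 && j2cp == 0.0 && j2cm == 0.0)) {
      s2 = R_PosInf;
    }
    s3 += sigma_term(j3p, j3m) * A;
    s4 += sigma_term(j4p, j4m) * A;
    memD += dsum * A;
    memE += yde[m] * A;
  }

  // diffusion dissipation over interior faces: A * D * (drho)^2 / (d * rho_bar)
  double sdiff[3] = {0, 0, 0};
  const double* rho[3] = {yDD, yDT, yE};
  const double Dco[3] = {DD, DD, DE};
  for (int s = 0; s < 3; ++s) {
    const double D = Dco[s];
    const double* r = rho[s];
    double acc = 0;
    for (int kz = 0; kz < Nz; ++kz) {
      const int off = Nr * kz;
      for (int i = 0; i < Nr - 1; ++i) {
        const double rbar = 0.5 * (r[off + i] + r[off + i + 1]);
        if (rbar > 0) {
          const double dl = r[off + i + 1] - r[off + i];
          acc += Ar[i] * D * dl * dl / (dr * rbar);
        }
      }
    }
    for (int kz = 0; kz < Nz - 1; ++kz) {
      for (int i = 0; i < Nr; ++i) {
        const int a = i + Nr * kz, b = a + Nr;
        const double rbar = 0.5 * (r[a] + r[b]);
        if (rbar > 0) {
          const double dl = r[b] - r[a];
          acc += Az[i] * D * dl * dl / (dz * rbar);
        }
      }
    }
    sdiff[s] = acc;
  }

  return List::create(
      _["J"] = NumericVector::create(_["J_1"] = J1, _["J_2"] = J2,
                                     _["J_2c"] = J2c, _["J_3"] = J3,
                                     _["J_4"] = J4),
      _["sigma_react"] = NumericVector::create(
          _["sigma_1"] = s1, _["sigma_2"] = s2, _["sigma_3"] = s3,
          _["sigma_4"] = s4),
      _["sigma_diff"] = NumericVector::create(
          _["DD"] = sdiff[0], _["DT"] = sdiff[1], _["E"] = sdiff[2]),
      _["counts"] = NumericVector::create(
          _["cytoplasm_MinD"] = cytD, _["cytoplasm_MinE"] = cytE,
          _["membrane_MinD"] = memD, _["membrane_MinE"] = memE));
}
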