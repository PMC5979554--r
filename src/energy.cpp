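// Hot paths of the docking engine: genotype -> pose kinematics and the
// pairwise energy sums. Mirrors the documented model exactly; the R test
// suite checks it against an independent plain-R summation.
#include <Rcpp.h>
using namespace Rcpp;

static inline double mehler_solmajer(double r) {
  return -8.5525 + 86.9525 / (1.0 + 7.7839 * std::exp(-0.3153767175 * r));
}

// Build ligand pose: torsions branch by branch (parents first), then global
// quaternion rotation about the rigid-root centroid, then translation.
// [[Rcpp::export]]
NumericMatrix cpp_build_pose(const NumericMatrix& ref,
                             const IntegerVector& root,
                             const IntegerVector& axis_from,
                             const IntegerVector& axis_to,
                             const List& subtrees,
                             const NumericVector& torsions,
                             const NumericVector& quat,
                             const NumericVector& target) {
  const int n = ref.nrow();
  NumericMatrix P(clone(ref));
  const int nb = axis_from.size();
  for (int b = 0; b < nb; ++b) {
    const double th = torsions[b];
    if (th == 0.0) continue;
    const int ia = axis_from[b] - 1, ib = axis_to[b] - 1;
    double ux = P(ib, 0) - P(ia, 0);
    double uy = P(ib, 1) - P(ia, 1);
    double uz = P(ib, 2) - P(ia, 2);
    const double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    if (nu < 1e-12) stop("degenerate torsion axis in branch %d", b + 1);
    ux /= nu; uy /= nu; uz /= nu;
    const double ct = std::cos(th), st = std::sin(th);
    const IntegerVector sub = subtrees[b];
    for (int k = 0; k < sub.size(); ++k) {
      const int i = sub[k] - 1;
      const double px = P(i, 0) - P(ia, 0);
      const double py = P(i, 1) - P(ia, 1);
      const double pz = P(i, 2) - P(ia, 2);
      const double dc = (px * ux + py * uy + pz * uz) * (1.0 - ct);
      P(i, 0) = P(ia, 0) + px * ct + (uy * pz - uz * py) * st + dc * ux;
      P(i, 1) = P(ia, 1) + py * ct + (uz * px - ux * pz) * st + dc * uy;
      P(i, 2) = P(ia, 2) + pz * ct + (ux * py - uy * px) * st + dc * uz;
    }
  }
  // root centroid
  double cx = 0, cy = 0, cz = 0;
  for (int k = 0; k < root.size(); ++k) {
    const int i = root[k] - 1;
    cx += P(i, 0); cy += P(i, 1); cz += P(i, 2);
  }
  cx /= root.size(); cy /= root.size(); cz /= root.size();
  // unit quaternion -> rotation matrix
  double qw = quat[0], qx = quat[1], qy = quat[2], qz = quat[3];
  const double qn = std::sqrt(qw * qw + qx * qx + qy * qy + qz * qz);
  if (qn < 1e-12) stop("degenerate orientation: zero quaternion");
  qw /= qn; qx /= qn; qy /= qn; qz /= qn;
  const double R00 = 1 - 2 * (qy * qy + qz * qz), R01 = 2 * (qx * qy - qw * qz),
               R02 = 2 * (qx * qz + qw * qy);
  const double R10 = 2 * (qx * qy + qw * qz), R11 = 1 - 2 * (qx * qx + qz * qz),
               R12 = 2 * (qy * qz - qw * qx);
  const double R20 = 2 * (qx * qz - qw * qy), R21 = 2 * (qy * qz + qw * qx),
               R22 = 1 - 2 * (qx * qx + qy * qy);
  for (int i = 0; i < n; ++i) {
    const double px = P(i, 0) - cx, py = P(i, 1) - cy, pz = P(i, 2) - cz;
    P(i, 0) = R00 * px + R01 * py + R02 * pz + target[0];
    P(i, 1) = R10 * px + R11 * py + R12 * pz + target[1];
    P(i, 2) = R20 * px + R21 * py + R22 * pz + target[2];
  }
  return P;
}

// Receptor-ligand pair sums. Coefficient vectors are flattened column-major
// (receptor index fastest), weights already folded in. diel <= 0 selects the
// Mehler-Solmajer screening function.
// [[Rcpp::export]]
NumericVector cpp_inter_terms(const NumericMatrix& rec,
                              const NumericMatrix& lig,
                              const NumericVector& cA, const NumericVector& cB,
                              const NumericVector& cC, const NumericVector& cD,
                              const NumericVector& cQQ,
                              const NumericVector& cSV,
                              double diel, double inv2sig2, double cut2) {
  const int nr = rec.nrow(), nl = lig.nrow();
  double vdw = 0, hb = 0, elec = 0, des = 0;
  int k = 0;
  for (int j = 0; j < nl; ++j) {
    const double lx = lig(j, 0), ly = lig(j, 1), lz = lig(j, 2);
    for (int i = 0; i < nr; ++i, ++k) {
      const double dx = rec(i, 0) - lx, dy = rec(i, 1) - ly,
                   dz = rec(i, 2) - lz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > cut2) continue;
      if (d2 < 1e-4) d2 = 1e-4;
      const double r = std::sqrt(d2);
      const double i2 = 1.0 / d2, i6 = i2 * i2 * i2, i12 = i6 * i6;
      vdw += cA[k] * i12 - cB[k] * i6;
      hb += cC[k] * i12 - cD[k] * i12 * d2;
      const double er = diel > 0 ? diel : mehler_solmajer(r);
      elec += cQQ[k] / (er * r);
      des += cSV[k] * std::exp(-d2 * inv2sig2);
    }
  }
  return NumericVector::create(_["vdw"] = vdw, _["hbond"] = hb,
                               _["elec"] = elec, _["desolv"] = des);
}

// Ligand-internal moving-pair sum (single total).
// [[Rcpp::export]]
double cpp_internal_energy(const NumericMatrix& lig,
                           const IntegerVector& ip, const IntegerVector& jp,
                           const NumericVector& mA, const NumericVector& mB,
                           const NumericVector& mC, const NumericVector& mD,
                           const NumericVector& mQQ, const NumericVector& mSV,
                           double diel, double inv2sig2) {
  double tot = 0;
  for (int k = 0; k < ip.size(); ++k) {
    const int i = ip[k] - 1, j = jp[k] - 1;
    const double dx = lig(i, 0) - lig(j, 0);
    const double dy = lig(i, 1) - lig(j, 1);
    const double dz = lig(i, 2) - lig(j, 2);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < 1e-4) d2 = 1e-4;
    const double r = std::sqrt(d2);
    const double i2 = 1.0 / d2, i6 = i2 * i2 * i2, i12 = i6 * i6;
    tot += mA[k] * i12 - mB[k] * i6;
    tot += mC[k] * i12 - mD[k] * i12 * d2;
    const double er = diel > 0 ? diel : mehler_solmajer(r);
    tot += mQQ[k] / (er * r);
    tot += mSV[k] * std::exp(-d2 * inv2sig2);
  }
  return tot;
}
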