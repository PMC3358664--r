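#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

namespace {

struct AlpbPar {
  double eps_in, eps_out, alpha, unit_factor;
};

AlpbPar as_alpb(const List& par) {
  AlpbPar p;
  p.eps_in = as<double>(par["eps_in"]);
  p.eps_out = as<double>(par["eps_out"]);
  p.alpha = as<double>(par["alpha"]);
  p.unit_factor = as<double>(par["unit_factor"]);
  return p;
}

// ALPB outside potential of one point charge at one vertex.
// d is recomputed from the displacement in working precision so that the
// single-precision mode rounds the whole kernel, not just the accumulation.
template <typename Real>
inline Real alpb_point(Real q, Real dx, Real dy, Real dz, Real r, const AlpbPar& p) {
  const Real one = static_cast<Real>(1);
  const Real d = std::sqrt(dx * dx + dy * dy + dz * dz);
  const Real alpha = static_cast<Real>(p.alpha);
  const Real beta = static_cast<Real>(p.eps_in) / static_cast<Real>(p.eps_out);
  const Real screen = one / (one + alpha * beta);
  const Real bracket = (one + alpha) / d - alpha * (one - beta) / r;
  return static_cast<Real>(p.unit_factor) * (q / static_cast<Real>(p.eps_in)) * screen * bracket;
}

template <typename Real>
List esp_exact_impl(const NumericMatrix& axyz, const NumericVector& aq,
                    const NumericMatrix& vxyz, const NumericVector& center,
                    const AlpbPar& p) {
  const int n = axyz.nrow(), np = vxyz.nrow();
  NumericVector pot(np);
  double calls = 0;
  for (int v = 0; v < np; ++v) {
    const double vx = vxyz(v, 0), vy = vxyz(v, 1), vz = vxyz(v, 2);
    const Real rx = static_cast<Real>(vx - center[0]);
    const Real ry = static_cast<Real>(vy - center[1]);
    const Real rz = static_cast<Real>(vz - center[2]);
    const Real r = std::sqrt(rx * rx + ry * ry + rz * rz);
    if (!(r > 0)) stop("vertex %d coincides with the reference center", v + 1);
    Real acc = 0;
    for (int a = 0; a < n; ++a) {
      const double dx = vx - axyz(a, 0), dy = vy - axyz(a, 1), dz = vz - axyz(a, 2);
      if (dx == 0 && dy == 0 && dz == 0)
        stop("vertex %d coincides with atom %d", v + 1, a + 1);
      acc += alpb_point<Real>(static_cast<Real>(aq[a]), static_cast<Real>(dx),
                              static_cast<Real>(dy), static_cast<Real>(dz), r, p);
      calls += 1;
    }
    pot[v] = static_cast<double>(acc);
  }
  return List::create(_["potentials"] = pot, _["kernel_calls"] = calls);
}

template <typename Real>
List esp_hcp_impl(const NumericMatrix& axyz, const NumericVector& aq,
                  const IntegerVector& atom_id,
                  const IntegerVector& res_ptr, const NumericMatrix& res_center,
                  const IntegerVector& str_ptr, const NumericMatrix& str_center,
                  const NumericVector& cplx_center,
                  const NumericMatrix& res_ac, const IntegerVector& res_ac_ptr,
                  const NumericMatrix& str_ac, const IntegerVector& str_ac_ptr,
                  const NumericMatrix& cplx_ac,
                  const NumericMatrix& vxyz, const NumericVector& center,
                  const double h_complex, const double h_strand, const double h_residue,
                  const AlpbPar& p) {
  const int np = vxyz.nrow();
  const int nstr = str_ptr.size() - 1;
  NumericVector pot(np);
  double calls = 0, use_cplx = 0, use_str = 0, use_res = 0, use_atom = 0;

  for (int v = 0; v < np; ++v) {
    const double vx = vxyz(v, 0), vy = vxyz(v, 1), vz = vxyz(v, 2);
    const Real rx = static_cast<Real>(vx - center[0]);
    const Real ry = static_cast<Real>(vy - center[1]);
    const Real rz = static_cast<Real>(vz - center[2]);
    const Real r = std::sqrt(rx * rx + ry * ry + rz * rz);
    if (!(r > 0)) stop("vertex %d coincides with the reference center", v + 1);
    Real acc = 0;

    // threshold tests always in double so both precision modes visit the
    // same charge sets (isolates rounding from path divergence)
    const double ccx = vx - cplx_center[0], ccy = vy - cplx_center[1], ccz = vz - cplx_center[2];
    const double dc = std::sqrt(ccx * ccx + ccy * ccy + ccz * ccz);

    if (dc > h_complex) {
      for (int k = 0; k < cplx_ac.nrow(); ++k) {
        const double dx = vx - cplx_ac(k, 0), dy = vy - cplx_ac(k, 1), dz = vz - cplx_ac(k, 2);
        if (dx == 0 && dy == 0 && dz == 0)
          stop("vertex %d coincides with a complex-level approximation charge", v + 1);
        acc += alpb_point<Real>(static_cast<Real>(cplx_ac(k, 3)), static_cast<Real>(dx),
                                static_cast<Real>(dy), static_cast<Real>(dz), r, p);
        calls += 1;
      }
      use_cplx += 1;
      pot[v] = static_cast<double>(acc);
      continue;
    }

    for (int s = 0; s < nstr; ++s) {
      const double sx = vx - str_center(s, 0), sy = vy - str_center(s, 1), sz = vz - str_center(s, 2);
      const double ds = std::sqrt(sx * sx + sy * sy + sz * sz);
      if (ds > h_strand) {
        for (int k = str_ac_ptr[s]; k < str_ac_ptr[s + 1]; ++k) {
          const double dx = vx - str_ac(k, 0), dy = vy - str_ac(k, 1), dz = vz - str_ac(k, 2);
          if (dx == 0 && dy == 0 && dz == 0)
            stop("vertex %d coincides with a strand-level approximation charge", v + 1);
          acc += alpb_point<Real>(static_cast<Real>(str_ac(k, 3)), static_cast<Real>(dx),
                                  static_cast<Real>(dy), static_cast<Real>(dz), r, p);
          calls += 1;
        }
        use_str += 1;
        continue;
      }
      for (int ri = str_ptr[s]; ri < str_ptr[s + 1]; ++ri) {
        const double rcx = vx - res_center(ri, 0), rcy = vy - res_center(ri, 1), rcz = vz - res_center(ri, 2);
        const double dr = std::sqrt(rcx * rcx + rcy * rcy + rcz * rcz);
        if (dr > h_residue) {
          for (int k = res_ac_ptr[ri]; k < res_ac_ptr[ri + 1]; ++k) {
            const double dx = vx - res_ac(k, 0), dy = vy - res_ac(k, 1), dz = vz - res_ac(k, 2);
            if (dx == 0 && dy == 0 && dz == 0)
              stop("vertex %d coincides with a residue-level approximation charge", v + 1);
            acc += alpb_point<Real>(static_cast<Real>(res_ac(k, 3)), static_cast<Real>(dx),
                                    static_cast<Real>(dy), static_cast<Real>(dz), r, p);
            calls += 1;
          }
          use_res += 1;
        } else {
          for (int a = res_ptr[ri]; a < res_ptr[ri + 1]; ++a) {
            const double dx = vx - axyz(a, 0), dy = vy - axyz(a, 1), dz = vz - axyz(a, 2);
            if (dx == 0 && dy == 0 && dz == 0)
              stop("vertex %d coincides with atom %d", v + 1, atom_id[a]);
            acc += alpb_point<Real>(static_cast<Real>(aq[a]), static_cast<Real>(dx),
                                    static_cast<Real>(dy), static_cast<Real>(dz), r, p);
            calls += 1;
            use_atom += 1;
          }
        }
      }
    }
    pot[v] = static_cast<double>(acc);
  }

  NumericVector usage = NumericVector::create(
      _["complex"] = use_cplx, _["strand"] = use_str,
      _["residue"] = use_res, _["atom"] = use_atom);
  return List::create(_["potentials"] = pot, _["kernel_calls"] = calls,
                      _["level_usage"] = usage);
}

}  // namespace

// [[Rcpp::export]]
List cpp_esp_exact(NumericMatrix axyz, NumericVector aq, NumericMatrix vxyz,
                   NumericVector center, List par, bool single_prec) {
  const AlpbPar p = as_alpb(par);
  if (single_prec) return esp_exact_impl<float>(axyz, aq, vxyz, center, p);
  return esp_exact_impl<double>(axyz, aq, vxyz, center, p);
}

// [[Rcpp::export]]
List cpp_esp_hcp(NumericMatrix axyz, NumericVector aq, IntegerVector atom_id,
                 IntegerVector res_ptr, NumericMatrix res_center,
                 IntegerVector str_ptr, NumericMatrix str_center,
                 NumericVector cplx_center,
                 NumericMatrix res_ac, IntegerVector res_ac_ptr,
                 NumericMatrix str_ac, IntegerVector str_ac_ptr,
                 NumericMatrix cplx_ac,
                 NumericMatrix vxyz, NumericVector center,
                 double h_complex, double h_strand, double h_residue,
                 List par, bool single_prec) {
  const AlpbPar p = as_alpb(par);
  if (single_prec)
    return esp_hcp_impl<float>(axyz, aq, atom_id, res_ptr, res_center, str_ptr,
                               str_center, cplx_center, res_ac, res_ac_ptr,
                               str_ac, str_ac_ptr, cplx_ac, vxyz, center,
                               h_complex, h_strand, h_residue, p);
  return esp_hcp_impl<double>(axyz, aq, atom_id, res_ptr, res_center, str_ptr,
                              str_center, cplx_center, res_ac, res_ac_ptr,
                              str_ac, str_ac_ptr, cplx_ac, vxyz, center,
                              h_complex, h_strand, h_residue, p);
}
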