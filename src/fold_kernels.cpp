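// Partition-function kernels for a nearest-neighbor RNA model.
//
// Two independent dynamic programs:
//  * fold_discrete_cpp  - McCaskill partition function of one discrete
//    sequence (scalar DP tables indexed by actual nucleotides).
//  * fold_expected_cpp  - expected partition function over a product of
//    categorical distributions Psi (n x 4).  Inside-table cells condition on
//    the nucleotide identities at the interval endpoints (4 x 4 per cell);
//    interior identities are marginalized as soon as no energy term can see
//    them.  A hand-written reverse-mode adjoint returns d log Z / d Psi.
//
// Both DPs store entries scaled by scale^-(span) (per-nucleotide scaling);
// n*log(scale) is added back to the reported log Z, so results are
// scale-invariant.  The adjoint supports diagonal checkpointing: inside
// tables are retained only every `checkpoint_every`-th diagonal (per parity
// chain, since the stack recursion couples span L to span L-2) and replayed
// on demand during the backward sweep.
//
// Energy terms enter as pre-exponentiated Boltzmann factors supplied from R:
//   wh[sz]        hairpin initiation weight, 0 below the minimum loop size
//   ws[a,b,c,d]   stack weight incl. pairability of both pairs
//   wbu[sz], win[sz]  bulge / internal initiation weights (0 past the cap)
//   au[a,b]       terminal non-GC closing penalty factor (1 for GC/CG)
//   pairable[a,b] 0/1
//   wa, wbm, wcm  multiloop closing / per-branch / per-unpaired factors
// Multiloop and exterior helices carry no terminal penalty; bulge and
// internal closings take it on both pairs; hairpins on their closing pair.

#include <Rcpp.h>
#include <cmath>
#include <cstddef>
#include <map>
#include <vector>

using namespace Rcpp;

namespace {

struct Model {
  std::vector<double> wh;    // size n+1, index = loop size
  std::vector<double> ws;    // 256, ((a*4+b)*4+c)*4+d
  std::vector<double> wbu;   // cap+1, index = loop size >= 1
  std::vector<double> win;   // cap+1, index = loop size >= 2
  std::vector<double> au;    // 16
  std::vector<int> pairable; // 16
  double wa, wbm, wcm;
  int theta, cap, n;
  double inv; // 1/scale

  static Model from_list(const List& w, int n) {
    Model m;
    m.wh = as<std::vector<double> >(w["wh"]);
    m.ws = as<std::vector<double> >(w["ws"]);
    m.wbu = as<std::vector<double> >(w["wbu"]);
    m.win = as<std::vector<double> >(w["win"]);
    m.au = as<std::vector<double> >(w["au"]);
    m.pairable = as<std::vector<int> >(w["pairable"]);
    m.wa = as<double>(w["wa"]);
    m.wbm = as<double>(w["wbm"]);
    m.wcm = as<double>(w["wcm"]);
    m.theta = as<int>(w["theta"]);
    m.cap = as<int>(w["cap"]);
    m.inv = 1.0 / as<double>(w["scale"]);
    m.n = n;
    return m;
  }
  double wib(int dl, int dr) const {
    int sz = dl + dr;
    if (sz < 1 || sz > cap) return 0.0;
    return (dl == 0 || dr == 0) ? wbu[sz] : win[sz];
  }
};

inline double ipow(double x, int k) {
  double r = 1.0;
  for (int i = 0; i < k; ++i) r *= x;
  return r;
}

} // namespace

// ---------------------------------------------------------------------------
// Discrete sequence kernel
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".fold_discrete_cpp")]]
double fold_discrete_cpp(IntegerVector seq, List weights) {
  const int n = seq.size();
  const Model M = Model::from_list(weights, n);
  const double inv = M.inv, inv2 = inv * inv;

  std::vector<double> Zb((size_t)n * n, 0.0), Zm1((size_t)n * n, 0.0),
      Zm((size_t)n * n, 0.0);

  for (int L = M.theta + 2; L <= n; ++L) {
    for (int i = 0; i + L - 1 < n; ++i) {
      const int j = i + L - 1;
      const int a = seq[i], b = seq[j];
      if (M.pairable[a * 4 + b]) {
        double v = M.wh[L - 2] * M.au[a * 4 + b] * ipow(inv, L);
        if (L - 2 >= M.theta + 2) {
          const int c = seq[i + 1], d = seq[j - 1];
          v += M.ws[((a * 4 + b) * 4 + c) * 4 + d] * Zb[(size_t)(i + 1) * n + (j - 1)] * inv2;
        }
        // bulge / internal
        double ib = 0.0;
        for (int dl = 0; dl <= M.cap; ++dl) {
          const int k = i + 1 + dl;
          if (k >= n) break;
          for (int dr = (dl == 0 ? 1 : 0); dl + dr <= M.cap; ++dr) {
            const int l = j - 1 - dr;
            if (l - k - 1 < M.theta) break;
            const double w = M.wib(dl, dr);
            if (w != 0.0) {
              const int c = seq[k], d = seq[l];
              if (M.pairable[c * 4 + d])
                ib += w * ipow(inv, dl + dr + 2) * M.au[c * 4 + d] *
                      Zb[(size_t)k * n + l];
            }
          }
        }
        v += M.au[a * 4 + b] * ib;
        // multiloop (>= 2 inner branches)
        double ml = 0.0;
        for (int k = i + 2; k <= j - 2; ++k) {
          const double z1 = Zm1[(size_t)k * n + (j - 1)];
          if (z1 != 0.0) ml += Zm[(size_t)(i + 1) * n + (k - 1)] * z1;
        }
        v += M.wa * M.wbm * inv2 * ml;
        Zb[(size_t)i * n + j] = v;
      }
      // Zm1: exactly one branch starting at i, trailing unpaired to j
      Zm1[(size_t)i * n + j] =
          (j > i ? Zm1[(size_t)i * n + (j - 1)] * M.wcm * inv : 0.0) +
          M.wbm * Zb[(size_t)i * n + j];
      // Zm: >= 1 branches on [i, j], last branch starts at k
      double zm = 0.0;
      for (int k = i; k <= j - M.theta - 1; ++k) {
        const double z1 = Zm1[(size_t)k * n + j];
        if (z1 == 0.0) continue;
        const double lead = ipow(M.wcm * inv, k - i) +
                            (k > i ? Zm[(size_t)i * n + (k - 1)] : 0.0);
        zm += lead * z1;
      }
      Zm[(size_t)i * n + j] = zm;
    }
  }

  // exterior
  std::vector<double> F(n, 0.0);
  for (int j = 0; j < n; ++j) {
    double f = (j > 0 ? F[j - 1] : 1.0) * inv;
    for (int i = 0; i <= j - M.theta - 1; ++i)
      f += (i > 0 ? F[i - 1] : 1.0) * Zb[(size_t)i * n + j];
    F[j] = f;
  }
  if (n == 0) return 0.0;
  return std::log(F[n - 1]) - n * std::log(inv);
}

// ---------------------------------------------------------------------------
// Expected partition kernel (forward + adjoint)
// ---------------------------------------------------------------------------

namespace {

// Inside table for one diagonal: cell i holds 16 values indexed a*4+b,
// conditional on the endpoint nucleotides of interval [i, i+L-1].
typedef std::vector<double> Diag;

struct ExpectedDP {
  const Model& M;
  const NumericMatrix& psi;
  int n;
  double inv, inv2;

  // fully retained scalar tables (i * n + j)
  std::vector<double> Zbm, Zbau, Zm1, Zm;
  std::vector<double> F;

  // retained inside diagonals (checkpoints and replay segments)
  std::map<int, Diag> zb;
  int ckpt; // checkpoint interval along each parity chain

  ExpectedDP(const Model& m, const NumericMatrix& p, int checkpoint_every)
      : M(m), psi(p), n(m.n), inv(m.inv), inv2(m.inv * m.inv),
        Zbm((size_t)n * n, 0.0), Zbau((size_t)n * n, 0.0),
        Zm1((size_t)n * n, 0.0), Zm((size_t)n * n, 0.0), F(n, 0.0),
        ckpt(checkpoint_every) {}

  bool is_checkpoint(int L) const {
    const int L0 = (((L - (M.theta + 2)) % 2) == 0) ? M.theta + 2 : M.theta + 3;
    return ((L - L0) / 2) % ckpt == 0;
  }

  // Compute inside diagonal L from diagonal L-2 (prev may be NULL when the
  // stack recursion cannot fire).  Scalar tables must already be filled for
  // all spans < L.
  Diag compute_diag(int L, const Diag* prev) const {
    const int ncell = n - L + 1;
    Diag out((size_t)ncell * 16, 0.0);
    const double hp_base = ipow(inv, L);
    for (int i = 0; i < ncell; ++i) {
      const int j = i + L - 1;
      const double hp = M.wh[L - 2] * hp_base;
      // bulge/internal sum over inner helix positions (au of the inner
      // closing pair is folded into Zbau)
      double ib = 0.0;
      for (int dl = 0; dl <= M.cap; ++dl) {
        const int k = i + 1 + dl;
        if (k >= n) break;
        for (int dr = (dl == 0 ? 1 : 0); dl + dr <= M.cap; ++dr) {
          const int l = j - 1 - dr;
          if (l - k - 1 < M.theta) break;
          const double w = M.wib(dl, dr);
          if (w != 0.0) ib += w * ipow(inv, dl + dr + 2) * Zbau[(size_t)k * n + l];
        }
      }
      double ml = 0.0;
      for (int k = i + 2; k <= j - 2; ++k) {
        const double z1 = Zm1[(size_t)k * n + (j - 1)];
        if (z1 != 0.0) ml += Zm[(size_t)(i + 1) * n + (k - 1)] * z1;
      }
      ml *= M.wa * M.wbm * inv2;

      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) {
          if (!M.pairable[a * 4 + b]) continue;
          double v = (hp + ib) * M.au[a * 4 + b] + ml;
          if (prev) {
            double s = 0.0;
            const double* zin = &(*prev)[(size_t)(i + 1) * 16];
            for (int c = 0; c < 4; ++c) {
              const double pc = psi(i + 1, c);
              if (pc == 0.0) continue;
              for (int d = 0; d < 4; ++d) {
                const double w = M.ws[((a * 4 + b) * 4 + c) * 4 + d];
                if (w != 0.0) s += w * pc * psi(j - 1, d) * zin[c * 4 + d];
              }
            }
            v += s * inv2;
          }
          out[(size_t)i * 16 + a * 4 + b] = v;
        }
    }
    return out;
  }

  // Fill scalar tables for diagonal L given its inside table.
  void fill_scalars(int L, const Diag& d) {
    const int ncell = n - L + 1;
    for (int i = 0; i < ncell; ++i) {
      const int j = i + L - 1;
      double sm = 0.0, sau = 0.0;
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) {
          if (!M.pairable[a * 4 + b]) continue;
          const double w = psi(i, a) * psi(j, b) * d[(size_t)i * 16 + a * 4 + b];
          sm += w;
          sau += w * M.au[a * 4 + b];
        }
      Zbm[(size_t)i * n + j] = sm;
      Zbau[(size_t)i * n + j] = sau;
      // Zm1 via the explicit sum (matches the adjoint below)
      double z1 = 0.0;
      for (int l = i + M.theta + 1; l <= j; ++l) {
        const double zb = Zbm[(size_t)i * n + l];
        if (zb != 0.0) z1 += zb * M.wbm * ipow(M.wcm * inv, j - l);
      }
      Zm1[(size_t)i * n + j] = z1;
      double zm = 0.0;
      for (int k = i; k <= j - M.theta - 1; ++k) {
        const double z1k = Zm1[(size_t)k * n + j];
        if (z1k == 0.0) continue;
        const double lead = ipow(M.wcm * inv, k - i) +
                            (k > i ? Zm[(size_t)i * n + (k - 1)] : 0.0);
        zm += lead * z1k;
      }
      Zm[(size_t)i * n + j] = zm;
    }
  }

  void forward(bool keep_diags) {
    const Diag* prev2[2] = {NULL, NULL}; // last diag per parity, when not keeping
    Diag hold[2];
    for (int L = M.theta + 2; L <= n; ++L) {
      const int par = L % 2;
      const Diag* prev = NULL;
      if (L - 2 >= M.theta + 2) {
        if (keep_diags) {
          std::map<int, Diag>::const_iterator it = zb.find(L - 2);
          prev = (it != zb.end()) ? &it->second : NULL; // always found (see below)
        } else {
          prev = prev2[par];
        }
      }
      Diag d = compute_diag(L, prev);
      fill_scalars(L, d);
      if (keep_diags) {
        // retain while the next same-parity diagonal still needs it; prune to
        // checkpoints afterwards
        zb[L].swap(d);
        if (L - 2 >= M.theta + 2 && !is_checkpoint(L - 2)) zb.erase(L - 2);
      } else {
        hold[par].swap(d);
        prev2[par] = &hold[par];
      }
    }
    for (int j = 0; j < n; ++j) {
      double f = (j > 0 ? F[j - 1] : 1.0) * inv;
      for (int i = 0; i <= j - M.theta - 1; ++i)
        f += (i > 0 ? F[i - 1] : 1.0) * Zbm[(size_t)i * n + j];
      F[j] = f;
    }
  }

  double log_z() const {
    if (n == 0) return 0.0;
    return std::log(F[n - 1]) - n * std::log(inv);
  }

  // Replay-on-demand access to inside diagonal L during the backward sweep.
  const Diag& ensure_diag(int L) {
    std::map<int, Diag>::iterator it = zb.find(L);
    if (it != zb.end()) return it->second;
    // nearest retained same-parity diagonal below L
    int c = -1;
    for (std::map<int, Diag>::iterator jt = zb.begin(); jt != zb.end(); ++jt)
      if (jt->first < L && ((L - jt->first) % 2 == 0)) c = jt->first;
    if (c < 0) stop("internal error: no checkpoint available for replay");
    for (int d = c + 2; d <= L; d += 2) {
      const Diag& prev = zb[d - 2];
      zb[d] = compute_diag(d, (d - 2 >= M.theta + 2) ? &prev : NULL);
    }
    return zb[L];
  }

  NumericMatrix backward() {
    NumericMatrix gpsi(n, 4);
    if (n < M.theta + 2) return gpsi;
    std::vector<double> bZbm((size_t)n * n, 0.0), bZbau((size_t)n * n, 0.0),
        bZm1((size_t)n * n, 0.0), bZm((size_t)n * n, 0.0), bF(n, 0.0);
    std::map<int, Diag> bzb;

    bF[n - 1] = 1.0 / F[n - 1]; // d log_z / d F[n-1]
    for (int j = n - 1; j >= 0; --j) {
      const double b = bF[j];
      if (b == 0.0) continue;
      if (j > 0) bF[j - 1] += b * inv;
      for (int i = 0; i <= j - M.theta - 1; ++i) {
        const double fi = (i > 0 ? F[i - 1] : 1.0);
        if (i > 0) bF[i - 1] += b * Zbm[(size_t)i * n + j];
        bZbm[(size_t)i * n + j] += b * fi;
      }
    }

    for (int L = n; L >= M.theta + 2; --L) {
      const Diag& dL = ensure_diag(L);
      const Diag* dL2 = (L - 2 >= M.theta + 2) ? &ensure_diag(L - 2) : NULL;
      Diag& barL = bzb[L];
      if (barL.empty()) barL.assign((size_t)(n - L + 1) * 16, 0.0);
      Diag* barL2 = NULL;
      if (dL2) {
        barL2 = &bzb[L - 2];
        if (barL2->empty()) barL2->assign((size_t)(n - (L - 2) + 1) * 16, 0.0);
      }
      const int ncell = n - L + 1;
      for (int i = 0; i < ncell; ++i) {
        const int j = i + L - 1;
        // Zm
        const double bm_ = bZm[(size_t)i * n + j];
        if (bm_ != 0.0) {
          for (int k = i; k <= j - M.theta - 1; ++k) {
            const double z1 = Zm1[(size_t)k * n + j];
            const double lead = ipow(M.wcm * inv, k - i) +
                                (k > i ? Zm[(size_t)i * n + (k - 1)] : 0.0);
            bZm1[(size_t)k * n + j] += bm_ * lead;
            if (k > i && z1 != 0.0) bZm[(size_t)i * n + (k - 1)] += bm_ * z1;
          }
        }
        // Zm1
        const double b1 = bZm1[(size_t)i * n + j];
        if (b1 != 0.0)
          for (int l = i + M.theta + 1; l <= j; ++l)
            bZbm[(size_t)i * n + l] += b1 * M.wbm * ipow(M.wcm * inv, j - l);
        // Zbm / Zbau -> inside table and psi at the endpoints
        const double bm = bZbm[(size_t)i * n + j], bau = bZbau[(size_t)i * n + j];
        if (bm != 0.0 || bau != 0.0) {
          for (int a = 0; a < 4; ++a)
            for (int b = 0; b < 4; ++b) {
              if (!M.pairable[a * 4 + b]) continue;
              const double t = bm + bau * M.au[a * 4 + b];
              const double v = dL[(size_t)i * 16 + a * 4 + b];
              barL[(size_t)i * 16 + a * 4 + b] += t * psi(i, a) * psi(j, b);
              gpsi(i, a) += t * psi(j, b) * v;
              gpsi(j, b) += t * psi(i, a) * v;
            }
        }
        // inside recursion of cell (i, j)
        double bvau = 0.0, bvsum = 0.0;
        for (int a = 0; a < 4; ++a)
          for (int b = 0; b < 4; ++b) {
            if (!M.pairable[a * 4 + b]) continue;
            const double bv = barL[(size_t)i * 16 + a * 4 + b];
            bvau += bv * M.au[a * 4 + b];
            bvsum += bv;
          }
        if (bvau != 0.0) {
          for (int dl = 0; dl <= M.cap; ++dl) {
            const int k = i + 1 + dl;
            if (k >= n) break;
            for (int dr = (dl == 0 ? 1 : 0); dl + dr <= M.cap; ++dr) {
              const int l = j - 1 - dr;
              if (l - k - 1 < M.theta) break;
              const double w = M.wib(dl, dr);
              if (w != 0.0)
                bZbau[(size_t)k * n + l] += bvau * w * ipow(inv, dl + dr + 2);
            }
          }
        }
        if (bvsum != 0.0) {
          const double cm = M.wa * M.wbm * inv2 * bvsum;
          for (int k = i + 2; k <= j - 2; ++k) {
            const double z1 = Zm1[(size_t)k * n + (j - 1)];
            const double zm = Zm[(size_t)(i + 1) * n + (k - 1)];
            if (z1 != 0.0) bZm[(size_t)(i + 1) * n + (k - 1)] += cm * z1;
            if (zm != 0.0) bZm1[(size_t)k * n + (j - 1)] += cm * zm;
          }
        }
        if (dL2) {
          for (int a = 0; a < 4; ++a)
            for (int b = 0; b < 4; ++b) {
              if (!M.pairable[a * 4 + b]) continue;
              const double bv = barL[(size_t)i * 16 + a * 4 + b];
              if (bv == 0.0) continue;
              for (int c = 0; c < 4; ++c) {
                const double pc = psi(i + 1, c);
                for (int d = 0; d < 4; ++d) {
                  const double w = M.ws[((a * 4 + b) * 4 + c) * 4 + d];
                  if (w == 0.0) continue;
                  const double pd = psi(j - 1, d);
                  const double v2 = (*dL2)[(size_t)(i + 1) * 16 + c * 4 + d];
                  (*barL2)[(size_t)(i + 1) * 16 + c * 4 + d] += bv * w * inv2 * pc * pd;
                  gpsi(i + 1, c) += bv * w * inv2 * pd * v2;
                  gpsi(j - 1, d) += bv * w * inv2 * pc * v2;
                }
              }
            }
        }
      }
      bzb.erase(L);
      zb.erase(L); // consumed; backward never revisits
    }
    return gpsi;
  }
};

} // namespace

// [[Rcpp::export(name = ".fold_expected_cpp")]]
List fold_expected_cpp(NumericMatrix psi, List weights, bool want_grad,
                       int checkpoint_every) {
  const int n = psi.nrow();
  Model M = Model::from_list(weights, n);
  if (checkpoint_every < 1) checkpoint_every = 1;
  ExpectedDP dp(M, psi, checkpoint_every);
  dp.forward(want_grad);
  const double lz = dp.log_z();
  if (!want_grad) return List::create(_["log_z"] = lz);
  NumericMatrix g = dp.backward();
  return List::create(_["log_z"] = lz, _["grad_psi"] = g);
}
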