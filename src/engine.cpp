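// Fused per-site history marginalization.
//
// Inputs are per-sample log-likelihood tables, transposed so one site's
// values are contiguous (ancestor: 10 x sites over diploid genotypes; each
// descendant: 4 x sites over haploid genotypes), plus the transmission /
// substitution weight matrices over (ancestral genotype g, outcome b). Per
// site everything is scaled by row maxima and combined in linear space;
// mutation mass uses the telescoping identity
//   prod_i s_i - prod_i nm_i = sum_i (prod_{j<i} s_j) m_i (prod_{j>i} nm_j)
// so small posteriors are sums of positive terms, not differences.
// Callability re-evaluates the posterior with one line's base labels
// cyclically shifted, which at the likelihood level is a column permutation
// of that line's table.

#include <Rcpp.h>
using namespace Rcpp;

static const int NG = 10;  // diploid genotypes
static const int NB = 4;   // bases

// [[Rcpp::export(name = ".engine_pass_cpp")]]
List engine_pass_cpp(NumericMatrix laT, List ldT,
                     NumericMatrix W, NumericMatrix WN, NumericMatrix WM,
                     NumericVector prior,
                     bool do_callable, double threshold, int min_strand,
                     List fwdT, List revT, IntegerVector shifts) {
  const int S = laT.ncol();
  const int n = ldT.size();
  std::vector<const double *> ldp;
  std::vector<const int *> fwp, rvp;
  for (int i = 0; i < n; ++i) ldp.push_back(REAL(as<NumericMatrix>(ldT[i])));
  if (do_callable) {
    for (int i = 0; i < n; ++i) {
      fwp.push_back(INTEGER(as<IntegerMatrix>(fwdT[i])));
      rvp.push_back(INTEGER(as<IntegerMatrix>(revT[i])));
    }
  }
  const double *lap = REAL(laT);
  double Wc[NG][NB], WNc[NG][NB], WMc[NG][NB];
  double pr[NG];
  for (int g = 0; g < NG; ++g) {
    pr[g] = prior[g];
    for (int b = 0; b < NB; ++b) {
      Wc[g][b] = W(g, b); WNc[g][b] = WN(g, b); WMc[g][b] = WM(g, b);
    }
  }
  int perm[/* line */ 16][NB];
  for (int i = 0; i < n && i < 16; ++i) {
    const int shift = shifts[i];
    for (int b = 0; b < NB; ++b) perm[i][b] = ((b - shift) % NB + NB) % NB;
  }
  if (n > 16) stop("more than 16 descendant lines are not supported");

  NumericVector p_any(S), p_one(S), log_lik(S);
  NumericMatrix per_lineT(n, S);
  IntegerVector mutant_line(S), mutant_allele(S);
  LogicalMatrix callableT(do_callable ? n : 1, do_callable ? S : 1);
  NumericMatrix p_shufT(do_callable ? n : 1, do_callable ? S : 1);
  IntegerMatrix am_shufT(do_callable ? n : 1, do_callable ? S : 1);

  std::vector<double> eld(n * NB), sv(n * NG), nmv(n * NG), mv(n * NG);
  std::vector<double> sufS(n * NG), sufNM(n * NG);
  double B[NG], preSB[NG], preNMB[NG], coeffB[NG];

  for (int s = 0; s < S; ++s) {
    const double *las = lap + (size_t)s * NG;
    double ma = R_NegInf;
    for (int g = 0; g < NG; ++g) ma = std::max(ma, las[g]);
    double log_scale;
    if (R_finite(ma)) {
      for (int g = 0; g < NG; ++g) B[g] = std::exp(las[g] - ma) * pr[g];
      log_scale = ma;
    } else {
      std::fill(B, B + NG, 0.0);
      log_scale = R_NegInf;
    }
    for (int i = 0; i < n; ++i) {
      const double *lds = ldp[i] + (size_t)s * NB;
      double mi = R_NegInf;
      for (int b = 0; b < NB; ++b) mi = std::max(mi, lds[b]);
      double *e = &eld[i * NB];
      if (R_finite(mi)) {
        for (int b = 0; b < NB; ++b) e[b] = std::exp(lds[b] - mi);
        log_scale += mi;
      } else {
        for (int b = 0; b < NB; ++b) e[b] = 0.0;
        log_scale = R_NegInf;
      }
      for (int g = 0; g < NG; ++g) {
        double ss = 0.0, nn = 0.0, mm = 0.0;
        for (int b = 0; b < NB; ++b) {
          ss += Wc[g][b] * e[b];
          nn += WNc[g][b] * e[b];
          mm += WMc[g][b] * e[b];
        }
        sv[i * NG + g] = ss;
        nmv[i * NG + g] = nn;
        mv[i * NG + g] = mm;
      }
    }
    // suffix products over lines (entry i = product over j > i)
    {
      double accS[NG], accNM[NG];
      for (int g = 0; g < NG; ++g) { accS[g] = 1.0; accNM[g] = 1.0; }
      for (int i = n - 1; i >= 0; --i) {
        for (int g = 0; g < NG; ++g) {
          sufS[i * NG + g] = accS[g];
          sufNM[i * NG + g] = accNM[g];
          accS[g] *= sv[i * NG + g];
          accNM[g] *= nmv[i * NG + g];
        }
      }
    }
    // forward pass; the ancestor term B is folded into the prefix products
    double mm_tot = 0.0, one_tot = 0.0, nm_tot = 0.0;
    for (int g = 0; g < NG; ++g) { preSB[g] = B[g]; preNMB[g] = B[g]; }
    double best_pl = -1.0; int best_line = -1; int best_allele = 0;
    for (int i = 0; i < n; ++i) {
      double pl = 0.0;
      double cwv[NB], al_score[NB];
      for (int g = 0; g < NG; ++g) {
        const double t_nm = mv[i * NG + g] * sufNM[i * NG + g];
        mm_tot += preSB[g] * t_nm;
        one_tot += preNMB[g] * t_nm;
        coeffB[g] = preSB[g] * sufS[i * NG + g];
      }
      const double *e = &eld[i * NB];
      for (int b = 0; b < NB; ++b) {
        double cw = 0.0;
        for (int g = 0; g < NG; ++g) cw += coeffB[g] * WMc[g][b];
        cwv[b] = cw;
        al_score[b] = cw * e[b];
        pl += al_score[b];
      }
      per_lineT(i, s) = pl;
      int am = 0;
      for (int b = 1; b < NB; ++b) if (al_score[b] > al_score[am]) am = b;
      if (pl > best_pl) { best_pl = pl; best_line = i; best_allele = am; }
      if (do_callable) {
        const int *pm = perm[i];
        double z_v = 0.0, nm_v = 0.0, alsh[NB];
        double ep[NB];
        for (int b = 0; b < NB; ++b) ep[b] = e[pm[b]];
        for (int g = 0; g < NG; ++g) {
          double ss = 0.0, nn = 0.0;
          for (int b = 0; b < NB; ++b) {
            ss += Wc[g][b] * ep[b];
            nn += WNc[g][b] * ep[b];
          }
          z_v += preSB[g] * ss * sufS[i * NG + g];
          nm_v += preNMB[g] * nn * sufNM[i * NG + g];
        }
        for (int b = 0; b < NB; ++b) alsh[b] = cwv[b] * ep[b];
        int asv = 0;
        for (int b = 1; b < NB; ++b) if (alsh[b] > alsh[asv]) asv = b;
        am_shufT(i, s) = asv + 1;
        if (z_v > 0.0) {
          double pv = (z_v - nm_v) / z_v;
          if (pv < 0.0) pv = 0.0;
          p_shufT(i, s) = pv;
          const int fs = fwp[i][(size_t)s * NB + pm[asv]];
          const int rs = rvp[i][(size_t)s * NB + pm[asv]];
          callableT(i, s) = (pv > threshold) && (fs >= min_strand) && (rs >= min_strand);
        } else {
          p_shufT(i, s) = NA_REAL;
          callableT(i, s) = false;
        }
      }
      for (int g = 0; g < NG; ++g) {
        preSB[g] *= sv[i * NG + g];
        preNMB[g] *= nmv[i * NG + g];
      }
    }
    // preNMB now holds B * prod over all lines of nm: the no-mutation mass
    for (int g = 0; g < NG; ++g) nm_tot += preNMB[g];
    const double z = mm_tot + nm_tot;
    if (z > 0.0) {
      p_any[s] = mm_tot / z;
      p_one[s] = one_tot / z;
      for (int i = 0; i < n; ++i) per_lineT(i, s) /= z;
      log_lik[s] = std::log(z) + log_scale;
      if (p_any[s] > 0.0 && best_line >= 0) {
        mutant_line[s] = best_line + 1;
        mutant_allele[s] = best_allele + 1;
      } else {
        mutant_line[s] = NA_INTEGER;
        mutant_allele[s] = NA_INTEGER;
      }
    } else {
      p_any[s] = NA_REAL; p_one[s] = NA_REAL;
      log_lik[s] = R_NegInf;
      for (int i = 0; i < n; ++i) per_lineT(i, s) = NA_REAL;
      mutant_line[s] = NA_INTEGER;
      mutant_allele[s] = NA_INTEGER;
    }
  }
  List out = List::create(
    _["p_any"] = p_any, _["p_one"] = p_one, _["per_lineT"] = per_lineT,
    _["mutant_line"] = mutant_line, _["mutant_allele"] = mutant_allele,
    _["log_lik"] = log_lik);
  if (do_callable) {
    out["callableT"] = callableT;
    out["p_shufT"] = p_shufT;
    out["am_shufT"] = am_shufT;
  }
  return out;
}
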