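#include <Rcpp.h>
using namespace Rcpp;

// One-sided discrete-Poisson log-likelihood ratio for a scanning window.
// dir: +1 = high (c > E required), -1 = low (c < E required).
// 0*log(0) convention handled; degenerate E returns 0 (guarded in R too).
static inline double pois_llr(double c, double E, double C, int dir) {
  if (E <= 0.0 || E >= C) return 0.0;
  if (dir > 0 ? (c <= E) : (c >= E)) return 0.0;
  double t1 = (c > 0.0) ? c * std::log(c / E) : 0.0;
  double rem = C - c;
  double t2 = (rem > 0.0) ? rem * std::log(rem / (C - E)) : 0.0;
  double v = t1 + t2;
  return v > 0.0 ? v : 0.0;
}

// Per-window statistics over the full candidate set. Windows are encoded as
// prefixes of each centre's distance-ordered neighbour list:
// offsets (0-based, length ncentres+1) delimits each centre's slice of nbr
// (0-based cell row indices); cumpop holds the running population sum.
// [[Rcpp::export]]
List scan_windows_cpp(IntegerVector offsets, IntegerVector nbr,
                      NumericVector cumpop, NumericVector cases_per_cell,
                      double C, double P, int dir) {
  int ncentres = offsets.size() - 1;
  int nw = nbr.size();
  IntegerVector centre(nw), ksize(nw);
  NumericVector cobs(nw), Ew(nw), llr(nw);
  int w = 0;
  for (int i = 0; i < ncentres; ++i) {
    double csum = 0.0;
    for (int j = offsets[i]; j < offsets[i + 1]; ++j) {
      csum += cases_per_cell[nbr[j]];
      double E = C * cumpop[j] / P;
      centre[w] = i + 1;              // 1-based row index into the cell table
      ksize[w] = j - offsets[i] + 1;
      cobs[w] = csum;
      Ew[w] = E;
      llr[w] = pois_llr(csum, E, C, dir);
      ++w;
    }
  }
  return List::create(_["centre"] = centre, _["k"] = ksize, _["c"] = cobs,
                      _["E"] = Ew, _["llr"] = llr);
}

// Monte Carlo null distribution of the maximum LLR: each replication
// redistributes C cases multinomially with cell probabilities `prob` and
// records the maximum LLR over the same candidate window set. Uses R's RNG
// so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector scan_mc_max_llr_cpp(IntegerVector offsets, IntegerVector nbr,
                                  NumericVector cumpop, int C, double P,
                                  NumericVector prob, int nrep, int dir) {
  int ncentres = offsets.size() - 1;
  int ncells = prob.size();
  std::vector<int> counts(ncells);
  std::vector<double> p(prob.begin(), prob.end());
  NumericVector out(nrep);
  RNGScope scope;
  for (int r = 0; r < nrep; ++r) {
    rmultinom(C, p.data(), ncells, counts.data());
    double best = 0.0;
    for (int i = 0; i < ncentres; ++i) {
      double csum = 0.0;
      for (int j = offsets[i]; j < offsets[i + 1]; ++j) {
        csum += counts[nbr[j]];
        double v = pois_llr(csum, C * cumpop[j] / P, C, dir);
        if (v > best) best = v;
      }
    }
    out[r] = best;
  }
  return out;
}
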