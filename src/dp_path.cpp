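#include <Rcpp.h>
using namespace Rcpp;

// Time-ordered interaction-path dynamic programme.
//
// Rows are lattice times (increasing), columns are delay offsets
// (increasing). A path visits one traversable column per row subject to
// the time-ordering constraint tau[n] - tau[n-1] >= -1 lattice step, i.e.
// prev column <= current column + 1. A cell contributes gain - q if it is
// super-threshold and the delay changed, gain if super-threshold and the
// delay is unchanged, and 0 otherwise (sub-threshold cells are
// traversable at zero contribution; NA gain marks untraversable cells).
//
// Objective is lexicographic: maximise total contribution, then minimise
// the number of delay-change events, then minimise the cumulative |tau|
// (favouring persistent, minimal-delay interpretations). All three
// components are additive per step, so the lexicographic Bellman recursion
// is exact.
//
// anchor[n] > 0 pins row n to that (1-based) column.

static inline bool lex_better(double s1, int c1, double a1,
                              double s2, int c2, double a2) {
  if (s1 != s2) return s1 > s2;
  if (c1 != c2) return c1 < c2;
  return a1 < a2;
}

// [[Rcpp::export(name = ".dp_extract_path")]]
List dp_extract_path(NumericMatrix gain, LogicalMatrix super,
                     NumericVector abs_tau, double q,
                     IntegerVector anchor) {
  const int T = gain.nrow(), J = gain.ncol();
  if (super.nrow() != T || super.ncol() != J)
    stop("gain and super must have identical dimensions");
  if (abs_tau.size() != J) stop("abs_tau must have one entry per column");
  if (anchor.size() != T) stop("anchor must have one entry per row");

  const double NEG = -std::numeric_limits<double>::infinity();
  NumericMatrix score(T, J);
  IntegerMatrix changes(T, J), pred(T, J);
  NumericMatrix sumabs(T, J);
  std::fill(score.begin(), score.end(), NEG);
  std::fill(pred.begin(), pred.end(), -1);

  auto traversable = [&](int n, int j) {
    if (NumericMatrix::is_na(gain(n, j))) return false;
    if (anchor[n] > 0 && anchor[n] - 1 != j) return false;
    return true;
  };
  auto contrib = [&](int n, int j, bool changed) {
    if (!super(n, j)) return 0.0;
    return changed ? gain(n, j) - q : gain(n, j);
  };

  for (int j = 0; j < J; ++j) {
    if (!traversable(0, j)) continue;
    score(0, j) = contrib(0, j, false);
    changes(0, j) = 0;
    sumabs(0, j) = abs_tau[j];
    pred(0, j) = j; // self-start marker
  }

  for (int n = 1; n < T; ++n) {
    // prefix lexicographic best and runner-up of the previous row,
    // extended column by column so that column j sees prefix 0..j+1
    double b1s = NEG, b2s = NEG;
    int b1c = 0, b2c = 0, b1j = -1, b2j = -1;
    double b1a = 0, b2a = 0;
    int ext = -1; // highest previous-row column folded into the prefix
    auto fold = [&](int jp) {
      if (score(n - 1, jp) == NEG) return;
      double s = score(n - 1, jp);
      int c = changes(n - 1, jp);
      double a = sumabs(n - 1, jp);
      if (b1j < 0 || lex_better(s, c, a, b1s, b1c, b1a)) {
        b2s = b1s; b2c = b1c; b2a = b1a; b2j = b1j;
        b1s = s; b1c = c; b1a = a; b1j = jp;
      } else if (b2j < 0 || lex_better(s, c, a, b2s, b2c, b2a)) {
        b2s = s; b2c = c; b2a = a; b2j = jp;
      }
    };
    for (int j = 0; j < J; ++j) {
      int lim = std::min(j + 1, J - 1);
      while (ext < lim) fold(++ext);
      if (!traversable(n, j)) continue;
      // stay at the same delay
      bool ok_stay = score(n - 1, j) != NEG;
      double ss = NEG; int sc = 0; double sa = 0;
      if (ok_stay) {
        ss = score(n - 1, j) + contrib(n, j, false);
        sc = changes(n - 1, j);
        sa = sumabs(n - 1, j) + abs_tau[j];
      }
      // change delay: best previous column != j within the prefix
      double cs = NEG; int cc = 0; double ca = 0; int cj = -1;
      double ps; int pc; double pa; int pj = -1;
      if (b1j >= 0 && b1j != j) { ps = b1s; pc = b1c; pa = b1a; pj = b1j; }
      else if (b2j >= 0)        { ps = b2s; pc = b2c; pa = b2a; pj = b2j; }
      if (pj >= 0) {
        cs = ps + contrib(n, j, true);
        cc = pc + 1;
        ca = pa + abs_tau[j];
        cj = pj;
      }
      if (ok_stay && (cj < 0 || !lex_better(cs, cc, ca, ss, sc, sa))) {
        score(n, j) = ss; changes(n, j) = sc; sumabs(n, j) = sa; pred(n, j) = j;
      } else if (cj >= 0) {
        score(n, j) = cs; changes(n, j) = cc; sumabs(n, j) = ca; pred(n, j) = cj;
      }
    }
    bool any = false;
    for (int j = 0; j < J; ++j) if (score(n, j) != NEG) { any = true; break; }
    if (!any) stop("interaction-path lattice disconnected at row %d", n + 1);
  }

  // pick the lexicographically best terminal cell (ties: smaller |tau|,
  // then lower column index)
  int best = -1;
  for (int j = 0; j < J; ++j) {
    if (score(T - 1, j) == NEG) continue;
    if (best < 0 ||
        lex_better(score(T - 1, j), changes(T - 1, j), sumabs(T - 1, j),
                   score(T - 1, best), changes(T - 1, best), sumabs(T - 1, best)) ||
        (score(T - 1, j) == score(T - 1, best) &&
         changes(T - 1, j) == changes(T - 1, best) &&
         sumabs(T - 1, j) == sumabs(T - 1, best) &&
         abs_tau[j] < abs_tau[best]))
      best = j;
  }
  if (best < 0) stop("no feasible interaction path");

  IntegerVector path(T);
  int j = best;
  for (int n = T - 1; n >= 0; --n) {
    path[n] = j + 1;
    j = pred(n, j);
  }
  NumericVector cell_contrib(T);
  LogicalVector on_super(T);
  for (int n = 0; n < T; ++n) {
    int pj = path[n] - 1;
    bool changed = n > 0 && path[n] != path[n - 1];
    cell_contrib[n] = contrib(n, pj, changed);
    on_super[n] = super(n, pj);
  }
  return List::create(
    _["path"] = path,
    _["score"] = score(T - 1, best),
    _["n_changes"] = changes(T - 1, best),
    _["sum_abs_tau"] = sumabs(T - 1, best),
    _["cell_contrib"] = cell_contrib,
    _["on_super"] = on_super
  );
}
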