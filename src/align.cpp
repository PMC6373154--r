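#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap alignment over a precomputed position-score matrix C (n x m),
// where C(i,j) is the score of pairing position i of sequence/profile A with
// position j of B. A gap of length L costs open + L * extend.
// Tie-break in fill and traceback: diagonal > vertical (gap in B) >
// horizontal (gap in A); in local mode, restarting (score 0) is chosen only
// when strictly better than every continuation.

static const double NEG = -1e30;
static const double EPS = 1e-9;

// [[Rcpp::export]]
List affine_align_cpp(NumericMatrix C, double open, double ext, bool local) {
  const int n = C.nrow(), m = C.ncol();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = local ? 0.0 : NEG;
    X(i, 0) = local ? NEG : -(open + i * ext);
    Y(i, 0) = NEG;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = local ? 0.0 : NEG;
    Y(0, j) = local ? NEG : -(open + j * ext);
    X(0, j) = NEG;
  }

  double best = NEG; int bi = n, bj = m;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      double s = C(i - 1, j - 1) + diag;
      if (local && s < 0.0) s = 0.0;
      M(i, j) = s;
      X(i, j) = std::max(M(i - 1, j) - open - ext,
               std::max(X(i - 1, j) - ext, Y(i - 1, j) - open - ext));
      Y(i, j) = std::max(M(i, j - 1) - open - ext,
               std::max(Y(i, j - 1) - ext, X(i, j - 1) - open - ext));
      if (local && M(i, j) > best + EPS) { best = M(i, j); bi = i; bj = j; }
    }
  }

  double score; int state; // 0 = M, 1 = X, 2 = Y
  int i, j;
  if (local) {
    if (best <= EPS) { // no positive-scoring local alignment
      return List::create(_["score"] = 0.0,
                          _["a"] = IntegerVector(0), _["b"] = IntegerVector(0));
    }
    score = best; i = bi; j = bj; state = 0;
  } else {
    i = n; j = m;
    double vm = M(n, m), vx = X(n, m), vy = Y(n, m);
    if (vm >= vx - EPS && vm >= vy - EPS) { score = vm; state = 0; }
    else if (vx >= vy - EPS)              { score = vx; state = 1; }
    else                                  { score = vy; state = 2; }
  }

  std::vector<int> pa, pb; // positions, 0 = gap
  while (i > 0 || j > 0) {
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      double vm = M(i - 1, j - 1), vx = X(i - 1, j - 1), vy = Y(i - 1, j - 1);
      double top = std::max(vm, std::max(vx, vy));
      if (local && top <= EPS) break; // local alignment starts at this cell
      if      (vm >= vx - EPS && vm >= vy - EPS) state = 0;
      else if (vx >= vy - EPS)                   state = 1;
      else                                       state = 2;
      --i; --j;
    } else if (state == 1) { // gap in B, consume A
      pa.push_back(i); pb.push_back(0);
      double vm = M(i - 1, j) - open - ext;
      double vx = X(i - 1, j) - ext;
      double vy = Y(i - 1, j) - open - ext;
      if      (vm >= vx - EPS && vm >= vy - EPS) state = 0;
      else if (vx >= vy - EPS)                   state = 1;
      else                                       state = 2;
      --i;
    } else { // gap in A, consume B
      pa.push_back(0); pb.push_back(j);
      double vm = M(i, j - 1) - open - ext;
      double vy = Y(i, j - 1) - ext;
      double vx = X(i, j - 1) - open - ext;
      if      (vm >= vx - EPS && vm >= vy - EPS) state = 0;
      else if (vy >= vx - EPS)                   state = 2;
      else                                       state = 1;
      --j;
    }
    if (i == 0 && j == 0) break;
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["a"] = wrap(pa), _["b"] = wrap(pb));
}
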