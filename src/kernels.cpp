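#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming kernels shared by the alignment and profile-HMM
// stages. Sequences arrive encoded as 0-based indices into the package's
// fixed amino-acid alphabet; negative values mark the ambiguity letter X.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Needleman-Wunsch global alignment with affine gaps.
// Gap of length L costs gap_open + L * gap_extend (both <= 0).
// Traceback tie-break: prefer diagonal (match), then up (gap in b),
// then left (gap in a).
// [[Rcpp::export]]
List cpp_nw_affine(IntegerVector a, IntegerVector b, NumericMatrix S,
                   double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // X: gap in b (consumes a, "up"); Y: gap in a (consumes b, "left").
  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = gap_open + i * gap_extend;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = gap_open + j * gap_extend;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sub = S(a[i - 1], b[j - 1]);
      double best = std::max(M(i - 1, j - 1),
                             std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = best + sub;
      X(i, j) = std::max(M(i - 1, j) + gap_open + gap_extend,
                         std::max(X(i - 1, j) + gap_extend,
                                  Y(i - 1, j) + gap_open + gap_extend));
      Y(i, j) = std::max(M(i, j - 1) + gap_open + gap_extend,
                         std::max(Y(i, j - 1) + gap_extend,
                                  X(i, j - 1) + gap_open + gap_extend));
    }
  }
  double score = std::max(M(n, m), std::max(X(n, m), Y(n, m)));

  // Traceback (prefer M, then X/up, then Y/left at every decision).
  std::vector<int> pa, pb;  // 1-based indices, 0 = gap
  int i = n, j = m;
  int state;  // 0 = M, 1 = X, 2 = Y
  if (M(n, m) >= X(n, m) && M(n, m) >= Y(n, m)) state = 0;
  else if (X(n, m) >= Y(n, m)) state = 1;
  else state = 2;
  while (i > 0 || j > 0) {
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      double prev = M(i, j) - S(a[i - 1], b[j - 1]);
      --i; --j;
      if (std::abs(M(i, j) - prev) < 1e-9) state = 0;
      else if (std::abs(X(i, j) - prev) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      double cur = X(i, j);
      --i;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) + gap_open + gap_extend - cur) < 1e-9) state = 0;
      else if (std::abs(X(i, j) + gap_extend - cur) < 1e-9) state = 1;
      else state = 2;
    } else {
      pa.push_back(0); pb.push_back(j);
      double cur = Y(i, j);
      --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) + gap_open + gap_extend - cur) < 1e-9) state = 0;
      else if (std::abs(Y(i, j) + gap_extend - cur) < 1e-9) state = 1;
      else state = 2;
    }
    if (i == 0 && j == 0) break;
    if (i == 0 && state != 2) state = 2;
    if (j == 0 && state != 1) state = 1;
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}

// Smith-Waterman best local alignment score (affine gaps, same gap model).
// [[Rcpp::export]]
double cpp_sw_score(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  std::vector<double> M(m + 1, 0.0), X(m + 1, NEG_INF), Y(m + 1, NEG_INF);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diagM = M[0], diagX = X[0], diagY = Y[0];
    M[0] = 0.0; X[0] = NEG_INF; Y[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      double keepM = M[j], keepX = X[j], keepY = Y[j];
      double sub = S(a[i - 1], b[j - 1]);
      double cand = std::max(diagM, std::max(diagX, diagY)) + sub;
      double newM = std::max(0.0, cand);
      double newX = std::max(keepM + gap_open + gap_extend,
                             std::max(keepX + gap_extend,
                                      keepY + gap_open + gap_extend));
      double newY = std::max(M[j - 1] + gap_open + gap_extend,
                             std::max(Y[j - 1] + gap_extend,
                                      X[j - 1] + gap_open + gap_extend));
      M[j] = newM; X[j] = newX; Y[j] = newY;
      diagM = keepM; diagX = keepX; diagY = keepY;
      if (newM > best) best = newM;
    }
  }
  return best;
}

// Local Viterbi log2-odds score of a sequence against a profile HMM.
//
// match_score: L x 21 matrix of log2(e_j(a)/bg(a)); column 21 (index 20)
//   is the score assigned to the ambiguity letter X (0 = neutral).
// trans: (L) x 7 matrix of log2 transition probabilities with columns
//   MM, MI, MD, IM, II, DM, DD; row j (1-based) holds transitions out of
//   match/insert/delete slot j into slot j+1. Row L is unused padding.
// Local model: free flanking residues, entry into any match state at cost
// log2(1/L), free exit after any match state.
// [[Rcpp::export]]
double cpp_viterbi(IntegerVector seq, NumericMatrix match_score,
                   NumericMatrix trans) {
  const int n = seq.size();
  const int L = match_score.nrow();
  const double entry = -std::log2((double) L);
  const double *ms = &match_score(0, 0);        // L x 21, column-major
  const double *tMM = &trans(0, 0);             // L x 7, column-major
  const double *tMI = tMM + L;
  const double *tMD = tMI + L;
  const double *tIM = tMD + L;
  const double *tII = tIM + L;
  const double *tDM = tII + L;
  const double *tDD = tDM + L;
  std::vector<double> Vm(L + 1), Vi(L + 1), Vd(L + 1);
  std::vector<double> Pm(L + 1, NEG_INF), Pi(L + 1, NEG_INF),
      Pd(L + 1, NEG_INF);
  double best = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    const int a = seq[i - 1];
    const double *em = ms + ((a < 0) ? 20 : a) * (size_t) L;
    double vm_prev = NEG_INF, vd_prev = NEG_INF;
    for (int j = 1; j <= L; ++j) {
      double cand = entry;  // fresh local start at match j
      if (j > 1) {
        double t;
        t = Pm[j - 1] + tMM[j - 2]; if (t > cand) cand = t;
        t = Pi[j - 1] + tIM[j - 2]; if (t > cand) cand = t;
        t = Pd[j - 1] + tDM[j - 2]; if (t > cand) cand = t;
      }
      const double vm = em[j - 1] + cand;
      // insert state j emits at background (score 0)
      const double vi = std::max(Pm[j] + tMI[j - 1], Pi[j] + tII[j - 1]);
      // delete state j consumes no residue: within-column recursion
      const double vd = (j > 1)
          ? std::max(vm_prev + tMD[j - 2], vd_prev + tDD[j - 2])
          : NEG_INF;
      Vm[j] = vm; Vi[j] = vi; Vd[j] = vd;
      vm_prev = vm; vd_prev = vd;
      if (vm > best) best = vm;  // free exit after any match state
    }
    std::swap(Vm, Pm); std::swap(Vi, Pi); std::swap(Vd, Pd);
  }
  return best;
}
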