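#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap alignment kernels over integer-encoded amino acids.
// Convention (matches NCBI/Biostrings): a gap of length L costs
// gap_open + L * gap_ext, i.e. the first gap position pays both.

static const double NEG = -1e12;

// state codes for traceback
enum { ST_M = 0, ST_X = 1, ST_Y = 2 };

// [[Rcpp::export]]
List cpp_local_align(IntegerVector q, IntegerVector t, IntegerMatrix sub,
                     double gap_open, double gap_ext) {
  int n = q.size(), m = t.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0);
  // full DP with traceback; three states, pointers packed into bytes
  std::vector<double> M((n + 1) * (m + 1), 0.0), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> ptr(3 * (n + 1) * (m + 1), 0);
  // ptr encoding: for M: 0=stop(local start),1=from M,2=from X,3=from Y
  //               for X: 1=open(from M),2=extend ; for Y likewise
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      int idx = i * (m + 1) + j;
      int diag = (i - 1) * (m + 1) + (j - 1);
      int up = (i - 1) * (m + 1) + j;
      int left = i * (m + 1) + (j - 1);
      double s = sub(qi, t[j - 1]);
      // X: gap in target (consume query residue)
      double xo = M[up] - gap_open - gap_ext;
      double xe = X[up] - gap_ext;
      if (xo >= xe) { X[idx] = xo; ptr[3 * idx + 1] = 1; }
      else          { X[idx] = xe; ptr[3 * idx + 1] = 2; }
      // Y: gap in query (consume target residue)
      double yo = M[left] - gap_open - gap_ext;
      double ye = Y[left] - gap_ext;
      if (yo >= ye) { Y[idx] = yo; ptr[3 * idx + 2] = 1; }
      else          { Y[idx] = ye; ptr[3 * idx + 2] = 2; }
      // M
      double mm = M[diag], from = 1;
      if (X[diag] > mm) { mm = X[diag]; from = 2; }
      if (Y[diag] > mm) { mm = Y[diag]; from = 3; }
      double v = mm + s;
      if (v <= 0.0) { M[idx] = 0.0; ptr[3 * idx] = 0; }
      else { M[idx] = v; ptr[3 * idx] = (unsigned char)from; }
      if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0);
  // traceback from (bi,bj) in state M
  std::vector<int> qidx, tidx;
  int i = bi, j = bj, st = ST_M;
  while (i > 0 && j > 0) {
    int idx = i * (m + 1) + j;
    if (st == ST_M) {
      unsigned char p = ptr[3 * idx];
      qidx.push_back(i - 1); tidx.push_back(j - 1);
      --i; --j;
      st = (p <= 1) ? ST_M : (p == 2 ? ST_X : ST_Y);
      // local alignment start: an M cell whose value is 0 with stop pointer
      if (st == ST_M) {
        int nidx = i * (m + 1) + j;
        if (ptr[3 * nidx] == 0) break;
      }
    } else if (st == ST_X) {
      unsigned char p = ptr[3 * idx + 1];
      qidx.push_back(i - 1); tidx.push_back(-1);
      --i;
      st = (p == 1) ? ST_M : ST_X;
    } else {
      unsigned char p = ptr[3 * idx + 2];
      qidx.push_back(-1); tidx.push_back(j - 1);
      --j;
      st = (p == 1) ? ST_M : ST_Y;
    }
  }
  std::reverse(qidx.begin(), qidx.end());
  std::reverse(tidx.begin(), tidx.end());
  int qs = -1, qe = -1, ts = -1, te = -1;
  for (size_t k = 0; k < qidx.size(); ++k) {
    if (qidx[k] >= 0) { if (qs < 0) qs = qidx[k]; qe = qidx[k]; }
    if (tidx[k] >= 0) { if (ts < 0) ts = tidx[k]; te = tidx[k]; }
  }
  return List::create(_["score"] = best,
                      _["qstart"] = qs, _["qend"] = qe + 1,
                      _["tstart"] = ts, _["tend"] = te + 1,
                      _["qidx"] = wrap(qidx), _["tidx"] = wrap(tidx));
}

// [[Rcpp::export]]
double cpp_global_score(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                        double gap_open, double gap_ext) {
  int n = a.size(), m = b.size();
  std::vector<double> M(m + 1), X(m + 1), Y(m + 1), Mp(m + 1), Xp(m + 1), Yp(m + 1);
  Mp[0] = 0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = -gap_open - gap_ext * j;
  }
  for (int i = 1; i <= n; ++i) {
    M[0] = NEG; Y[0] = NEG; X[0] = -gap_open - gap_ext * i;
    for (int j = 1; j <= m; ++j) {
      double s = sub(a[i - 1], b[j - 1]);
      double prev = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      M[j] = prev + s;
      X[j] = std::max(Mp[j] - gap_open - gap_ext, Xp[j] - gap_ext);
      Y[j] = std::max(M[j - 1] - gap_open - gap_ext, Y[j - 1] - gap_ext);
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  return std::max(Mp[m], std::max(Xp[m], Yp[m]));
}

// [[Rcpp::export]]
List cpp_global_align(IntegerVector a, IntegerVector b, IntegerMatrix sub,
                      double gap_open, double gap_ext) {
  int n = a.size(), m = b.size();
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> ptr(3 * (n + 1) * (m + 1), 0);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    int idx = i * (m + 1);
    X[idx] = -gap_open - gap_ext * i;
    ptr[3 * idx + 1] = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -gap_open - gap_ext * j;
    ptr[3 * j + 2] = (j == 1) ? 1 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int idx = i * (m + 1) + j;
      int diag = (i - 1) * (m + 1) + (j - 1);
      int up = (i - 1) * (m + 1) + j;
      int left = i * (m + 1) + (j - 1);
      double s = sub(a[i - 1], b[j - 1]);
      double xo = M[up] - gap_open - gap_ext, xe = X[up] - gap_ext;
      if (xo >= xe) { X[idx] = xo; ptr[3 * idx + 1] = 1; }
      else          { X[idx] = xe; ptr[3 * idx + 1] = 2; }
      double yo = M[left] - gap_open - gap_ext, ye = Y[left] - gap_ext;
      if (yo >= ye) { Y[idx] = yo; ptr[3 * idx + 2] = 1; }
      else          { Y[idx] = ye; ptr[3 * idx + 2] = 2; }
      double mm = M[diag]; unsigned char from = 1;
      if (X[diag] > mm) { mm = X[diag]; from = 2; }
      if (Y[diag] > mm) { mm = Y[diag]; from = 3; }
      M[idx] = mm + s; ptr[3 * idx] = from;
    }
  }
  int endidx = n * (m + 1) + m;
  double sc = M[endidx]; int st = ST_M;
  if (X[endidx] > sc) { sc = X[endidx]; st = ST_X; }
  if (Y[endidx] > sc) { sc = Y[endidx]; st = ST_Y; }
  std::vector<int> qidx, tidx;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int idx = i * (m + 1) + j;
    if (st == ST_M) {
      unsigned char p = ptr[3 * idx];
      qidx.push_back(i - 1); tidx.push_back(j - 1);
      --i; --j;
      st = (p == 1) ? ST_M : (p == 2 ? ST_X : ST_Y);
    } else if (st == ST_X) {
      unsigned char p = ptr[3 * idx + 1];
      qidx.push_back(i - 1); tidx.push_back(-1);
      --i;
      st = (p == 1) ? ST_M : ST_X;
    } else {
      unsigned char p = ptr[3 * idx + 2];
      qidx.push_back(-1); tidx.push_back(j - 1);
      --j;
      st = (p == 1) ? ST_M : ST_Y;
    }
  }
  std::reverse(qidx.begin(), qidx.end());
  std::reverse(tidx.begin(), tidx.end());
  return List::create(_["score"] = sc, _["qidx"] = wrap(qidx),
                      _["tidx"] = wrap(tidx));
}

// Seeded extension windows on one frame translation, BLAST-style:
// query words are expanded into their scoring neighborhood (all words
// with ungapped word score >= threshold, over the 20 standard residues),
// the target is scanned against that index, and a seed is confirmed when
// two word hits fall on the same diagonal within `two_hit_dist`
// (require_two = FALSE confirms every hit). Confirmed seeds are
// clustered by target position; each cluster yields a window
// [start, end) on the target that covers any alignment through its
// seeds, expanded by `margin`. threshold = -Inf short-circuits to one
// window spanning the whole target (guaranteed seed).
// Confirmed seeds then undergo ungapped X-drop extension along their
// diagonal; only extensions scoring >= trigger open a gapped window
// (trigger <= 0 disables that stage).
// [[Rcpp::export]]
IntegerMatrix cpp_seed_windows(IntegerVector q, IntegerVector t,
                               IntegerMatrix sub, int k, double threshold,
                               int two_hit_dist, bool require_two,
                               int win_gap, int margin, double trigger,
                               double xdrop) {
  int n = q.size(), m = t.size();
  if (m < k || n < k) return IntegerMatrix(0, 2);
  if (threshold == R_NegInf) {
    IntegerMatrix w(1, 2);
    w(0, 0) = 0; w(0, 1) = m;
    return w;
  }
  const int A = 20;                 // standard residue alphabet size
  const int NW = A * A * A;         // k is fixed to 3 for the word index
  // neighborhood index: word -> query positions scoring >= threshold
  std::vector<std::vector<int> > bucket(NW);
  {
    std::vector<double> s1(A), s2(A);
    for (int i = 0; i + k <= n; ++i) {
      int q0 = q[i], q1 = q[i + 1], q2 = q[i + 2];
      for (int a = 0; a < A; ++a) s1[a] = sub(q0, a);
      for (int a = 0; a < A; ++a) s2[a] = sub(q1, a);
      for (int a = 0; a < A; ++a) {
        double sa = s1[a];
        if (sa + 22 < threshold) continue;  // 11 is the matrix maximum
        for (int b = 0; b < A; ++b) {
          double sab = sa + s2[b];
          for (int c = 0; c < A; ++c) {
            if (sab + sub(q2, c) >= threshold)
              bucket[(a * A + b) * A + c].push_back(i);
          }
        }
      }
    }
  }
  // diagonal bookkeeping: two-hit rule + skip of already-extended spans
  std::vector<int> last_hit(n + m + 1, -1000000);
  std::vector<int> ext_until(n + m + 1, -1000000);
  std::vector<int> seed_t, seed_q;   // trigger segments (start coords)
  std::vector<int> seed_e, seed_qe;  // their end coords
  for (int j = 0; j + k <= m; ++j) {
    int a = t[j], b = t[j + 1], c = t[j + 2];
    if (a >= A || b >= A || c >= A) continue;  // X/* /mask: no seeding
    const std::vector<int> &qs = bucket[(a * A + b) * A + c];
    for (size_t z = 0; z < qs.size(); ++z) {
      int i = qs[z];
      int d = j - i + n;
      bool confirmed = !require_two ||
        (j - last_hit[d] > 0 && j - last_hit[d] <= two_hit_dist);
      last_hit[d] = j;
      if (!confirmed || j < ext_until[d]) continue;
      if (trigger <= 0) {
        seed_t.push_back(j); seed_q.push_back(i);
        seed_e.push_back(j + k); seed_qe.push_back(i + k);
        continue;
      }
      // ungapped X-drop extension along diagonal d
      double sc = 0.0;
      for (int z2 = 0; z2 < k; ++z2) sc += sub(q[i + z2], t[j + z2]);
      double best = sc;
      int bl = 0, br = 0;  // extension offsets of the best segment
      double cur = sc;
      for (int o = 1; i - o >= 0 && j - o >= 0; ++o) {  // leftwards
        cur += sub(q[i - o], t[j - o]);
        if (cur > best) { best = cur; bl = o; }
        if (cur < best - xdrop) break;
      }
      cur = best;
      for (int o = 0; i + k + o < n && j + k + o < m; ++o) {  // rightwards
        cur += sub(q[i + k + o], t[j + k + o]);
        if (cur > best) { best = cur; br = o + 1; }
        if (cur < best - xdrop) break;
      }
      ext_until[d] = j + k + br;
      if (best >= trigger) {
        seed_t.push_back(j - bl); seed_q.push_back(i - bl);
        seed_e.push_back(j + k + br); seed_qe.push_back(i + k + br);
      }
    }
  }
  if (seed_t.empty()) return IntegerMatrix(0, 2);
  // cluster by target position (seed_t is non-decreasing)
  std::vector<int> ws, we;
  int cs = seed_t[0] - seed_q[0];
  int ce = seed_e[0] + (n - seed_qe[0]);
  int prev = seed_e[0];
  for (size_t z = 1; z < seed_t.size(); ++z) {
    if (seed_t[z] - prev > win_gap) {
      ws.push_back(cs); we.push_back(ce);
      cs = seed_t[z] - seed_q[z];
      ce = seed_e[z] + (n - seed_qe[z]);
      prev = seed_e[z];
    } else {
      cs = std::min(cs, seed_t[z] - seed_q[z]);
      ce = std::max(ce, seed_e[z] + (n - seed_qe[z]));
      prev = std::max(prev, seed_e[z]);
    }
  }
  ws.push_back(cs); we.push_back(ce);
  IntegerMatrix out(ws.size(), 2);
  for (size_t z = 0; z < ws.size(); ++z) {
    out(z, 0) = std::max(0, ws[z] - margin);
    out(z, 1) = std::min(m, we[z] + k + margin);
  }
  return out;
}
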