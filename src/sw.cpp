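#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps: a gap of length k costs
// open + k * ext (BLAST convention: existence 11, extension 1 => 11 + k).
// Sequences arrive as 0-based integer indices into the substitution matrix.
//
// Traceback state codes for H: 0 stop, 1 diagonal, 2 from E (gap in query /
// vertical), 3 from F (gap in target / horizontal). E and F each record
// whether they were opened from H (0) or extended (1).

struct AlnStats {
  int score;
  int cols;      // residue-residue columns
  int ident;     // identical residue-residue columns
  int qstart, qend, tstart, tend;  // 0-based half-open spans
};

static AlnStats sw_one(const int *q, int m, const int *t, int n,
                       const IntegerMatrix &S, int open, int ext) {
  const int W = n + 1;
  std::vector<int> H((size_t)(m + 1) * W, 0), E(H), F(H);
  std::vector<unsigned char> ptrH((size_t)(m + 1) * W, 0), ptrE(ptrH), ptrF(ptrH);
  const int NEG = INT_MIN / 4;
  for (int j = 0; j <= n; ++j) { E[j] = NEG; F[j] = NEG; }

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    E[(size_t)i * W] = NEG;
    F[(size_t)i * W] = NEG;
    for (int j = 1; j <= n; ++j) {
      const size_t k = (size_t)i * W + j, ku = k - W, kl = k - 1;
      // E: gap in target consuming query residue i (vertical move)
      int eo = H[ku] - open - ext, ee = E[ku] - ext;
      if (eo >= ee) { E[k] = eo; ptrE[k] = 0; } else { E[k] = ee; ptrE[k] = 1; }
      // F: gap in query consuming target residue j (horizontal move)
      int fo = H[kl] - open - ext, fe = F[kl] - ext;
      if (fo >= fe) { F[k] = fo; ptrF[k] = 0; } else { F[k] = fe; ptrF[k] = 1; }
      int d = H[ku - 1] + S(q[i - 1], t[j - 1]);
      int h = 0; unsigned char p = 0;
      if (d > h) { h = d; p = 1; }
      if (E[k] > h) { h = E[k]; p = 2; }
      if (F[k] > h) { h = F[k]; p = 3; }
      H[k] = h; ptrH[k] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  AlnStats st; st.score = best; st.cols = 0; st.ident = 0;
  int i = bi, j = bj;
  st.qend = bi; st.tend = bj;
  int state = 0;  // 0 = in H, 1 = in E, 2 = in F
  while (i > 0 && j > 0) {
    const size_t k = (size_t)i * W + j;
    if (state == 0) {
      unsigned char p = ptrH[k];
      if (p == 0) break;
      if (p == 1) {
        ++st.cols;
        if (q[i - 1] == t[j - 1]) ++st.ident;
        --i; --j;
      } else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (ptrE[k] == 0) state = 0;
      --i;
    } else {
      if (ptrF[k] == 0) state = 0;
      --j;
    }
  }
  st.qstart = i; st.tstart = j;
  return st;
}

// [[Rcpp::export(name = ".sw_pair")]]
List sw_pair(IntegerVector q, IntegerVector t, IntegerMatrix S,
             int gap_open, int gap_ext) {
  AlnStats st = sw_one(q.begin(), q.size(), t.begin(), t.size(), S,
                       gap_open, gap_ext);
  return List::create(_["score"] = st.score, _["cols"] = st.cols,
                      _["ident"] = st.ident, _["qstart"] = st.qstart,
                      _["qend"] = st.qend, _["tstart"] = st.tstart,
                      _["tend"] = st.tend);
}

// All-vs-all alignment of two encoded proteomes; returns flat matrices
// (length(qs) x length(ts)) of score, identity columns, aligned columns and
// span lengths, from which hit filtering is done in R.
// [[Rcpp::export(name = ".sw_all")]]
List sw_all(List qs, List ts, IntegerMatrix S, int gap_open, int gap_ext) {
  const int nq = qs.size(), nt = ts.size();
  IntegerMatrix score(nq, nt), cols(nq, nt), ident(nq, nt),
      qspan(nq, nt), tspan(nq, nt);
  std::vector<std::vector<int>> Q(nq), T(nt);
  for (int a = 0; a < nq; ++a) Q[a] = as<std::vector<int>>(qs[a]);
  for (int b = 0; b < nt; ++b) T[b] = as<std::vector<int>>(ts[b]);
  for (int a = 0; a < nq; ++a) {
    Rcpp::checkUserInterrupt();
    for (int b = 0; b < nt; ++b) {
      AlnStats st = sw_one(Q[a].data(), (int)Q[a].size(), T[b].data(),
                           (int)T[b].size(), S, gap_open, gap_ext);
      score(a, b) = st.score;
      cols(a, b) = st.cols;
      ident(a, b) = st.ident;
      qspan(a, b) = st.qend - st.qstart;
      tspan(a, b) = st.tend - st.tstart;
    }
  }
  return List::create(_["score"] = score, _["cols"] = cols,
                      _["ident"] = ident, _["qspan"] = qspan,
                      _["tspan"] = tspan);
}
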