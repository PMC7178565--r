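// Numerical kernels for the 1D segmentation network and the aligner.
// Layout convention: signal tensors are cubes of dim (L, C, B) --
// time x channels x batch. GRU internals use (L*B, 3H) gate matrices
// with rows ordered time-major (row = t*B + b) so the input projection
// is a single GEMM.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// ---------------------------------------------------------------- conv1d

// 'same' padding im2col: M(t, o*Cin + c) = X(t + o - pad, c) or 0
static mat im2col(const mat& Xs, int k) {
  const int L = Xs.n_rows, Cin = Xs.n_cols, pad = (k - 1) / 2;
  mat M(L, k * Cin, fill::zeros);
  for (int o = 0; o < k; ++o) {
    int shift = o - pad;
    int t0 = std::max(0, -shift), t1 = std::min(L, L - shift);
    if (t0 >= t1) continue;
    M.submat(t0, o * Cin, t1 - 1, (o + 1) * Cin - 1) =
      Xs.rows(t0 + shift, t1 - 1 + shift);
  }
  return M;
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_fw(const arma::cube& X, const arma::mat& W,
                         const arma::rowvec& b, int k) {
  const int L = X.n_rows, B = X.n_slices, Cout = W.n_cols;
  cube Y(L, Cout, B);
  for (int s = 0; s < B; ++s) {
    mat M = im2col(X.slice(s), k);
    Y.slice(s) = M * W;
    Y.slice(s).each_row() += b;
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bw(const arma::cube& X, const arma::mat& W,
                         const arma::cube& dY, int k) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const int pad = (k - 1) / 2;
  cube dX(L, Cin, B, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  rowvec db(W.n_cols, fill::zeros);
  for (int s = 0; s < B; ++s) {
    mat M = im2col(X.slice(s), k);
    dW += M.t() * dY.slice(s);
    db += sum(dY.slice(s), 0);
    mat dM = dY.slice(s) * W.t();
    for (int o = 0; o < k; ++o) {
      int shift = o - pad;
      int t0 = std::max(0, -shift), t1 = std::min(L, L - shift);
      if (t0 >= t1) continue;
      dX.slice(s).rows(t0 + shift, t1 - 1 + shift) +=
        dM.submat(t0, o * Cin, t1 - 1, (o + 1) * Cin - 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// --------------------------------------------------------------- maxpool

// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fw(const arma::cube& X, int f) {
  const int L = X.n_rows, C = X.n_cols, B = X.n_slices, Lo = L / f;
  cube Y(Lo, C, B);
  ucube idx(Lo, C, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Lo; ++j) {
        int best = j * f;
        double bv = X(best, c, s);
        for (int o = 1; o < f; ++o)
          if (X(j * f + o, c, s) > bv) { bv = X(j * f + o, c, s); best = j * f + o; }
        Y(j, c, s) = bv;
        idx(j, c, s) = best;
      }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bw(const arma::ucube& idx, const arma::cube& dY,
                          int L) {
  const int Lo = dY.n_rows, C = dY.n_cols, B = dY.n_slices;
  cube dX(L, C, B, fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Lo; ++j)
        dX(idx(j, c, s), c, s) += dY(j, c, s);
  return dX;
}

// ----------------------------------------------------- bidirectional GRU
//
// Gate layout in the 3H axis: [update z | reset r | candidate c].
//   z_t = sigmoid(x_t W_z + h_{t-1} U_z + b_z)
//   r_t = sigmoid(x_t W_r + h_{t-1} U_r + b_r)
//   c_t = tanh   (x_t W_c + r_t .* (h_{t-1} U_c) + b_c)
//   h_t = z_t .* h_{t-1} + (1 - z_t) .* c_t

// flatten (L,Cin,B) -> (L*B, Cin), rows time-major
static mat flatten_tm(const cube& X) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  mat F(L * B, Cin);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < Cin; ++c)
      for (int t = 0; t < L; ++t)
        F(t * B + s, c) = X(t, c, s);
  return F;
}

static cube unflatten_tm(const mat& F, int L, int Cin, int B) {
  cube X(L, Cin, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < Cin; ++c)
      for (int t = 0; t < L; ++t)
        X(t, c, s) = F(t * B + s, c);
  return X;
}

struct GruCache { cube Z, R, C, HPC, H; };

// one direction; 'rev' scans the sequence right-to-left. Output hidden
// state is written into Y columns [col0, col0+H) at each physical time.
static void gru_dir_fw(const mat& G, const mat& U, int L, int B, int H,
                       bool rev, cube& Y, int col0, GruCache& cc) {
  cc.Z.set_size(B, H, L); cc.R.set_size(B, H, L); cc.C.set_size(B, H, L);
  cc.HPC.set_size(B, H, L); cc.H.set_size(B, H, L);
  mat h(B, H, fill::zeros), HP(B, 3 * H);
  const int n = B * H;
  for (int step = 0; step < L; ++step) {
    int t = rev ? (L - 1 - step) : step;
    HP = h * U;
    double* z = cc.Z.slice_memptr(step);
    double* r = cc.R.slice_memptr(step);
    double* c = cc.C.slice_memptr(step);
    double* hpc = cc.HPC.slice_memptr(step);
    double* hn = cc.H.slice_memptr(step);
    const double* hp = HP.memptr();
    const double* hold = h.memptr();
    // G rows for time t are not contiguous (row-block of a big matrix);
    // address column j of the block as G.colptr(j) + t*B
    for (int j = 0; j < 3 * H; ++j) {
      const double* gc = G.colptr(j) + (size_t)t * B;
      const double* hpj = hp + (size_t)j * B;
      if (j < H) {
        double* zj = z + (size_t)j * B;
        for (int s = 0; s < B; ++s) zj[s] = 1.0 / (1.0 + std::exp(-(gc[s] + hpj[s])));
      } else if (j < 2 * H) {
        double* rj = r + (size_t)(j - H) * B;
        for (int s = 0; s < B; ++s) rj[s] = 1.0 / (1.0 + std::exp(-(gc[s] + hpj[s])));
      } else {
        int jj = j - 2 * H;
        double* cj = c + (size_t)jj * B;
        double* hj = hpc + (size_t)jj * B;
        const double* rj = r + (size_t)jj * B;
        for (int s = 0; s < B; ++s) {
          hj[s] = hpj[s];
          cj[s] = std::tanh(gc[s] + rj[s] * hpj[s]);
        }
      }
    }
    for (int i = 0; i < n; ++i) hn[i] = z[i] * hold[i] + (1.0 - z[i]) * c[i];
    h = cc.H.slice(step);
    for (int s = 0; s < B; ++s)
      for (int j = 0; j < H; ++j)
        Y(t, col0 + j, s) = h(s, j);
  }
}

static void gru_dir_bw(const mat& U, int L, int B, int H, bool rev,
                       const cube& dY, int col0, const GruCache& cc,
                       mat& dG, mat& dU) {
  mat Uz = U.cols(0, H - 1), Ur = U.cols(H, 2 * H - 1), Uc = U.cols(2 * H, 3 * H - 1);
  mat dUz(size(Uz), fill::zeros), dUr(size(Ur), fill::zeros), dUc(size(Uc), fill::zeros);
  mat dh(B, H, fill::zeros);
  for (int step = L - 1; step >= 0; --step) {
    int t = rev ? (L - 1 - step) : step;
    for (int s = 0; s < B; ++s)
      for (int j = 0; j < H; ++j)
        dh(s, j) += dY(t, col0 + j, s);
    mat hprev = (step > 0) ? cc.H.slice(step - 1) : mat(B, H, fill::zeros);
    const mat& Z = cc.Z.slice(step);
    const mat& R = cc.R.slice(step);
    const mat& C = cc.C.slice(step);
    const mat& HPC = cc.HPC.slice(step);
    mat dz = dh % (hprev - C);
    mat daz = dz % Z % (1.0 - Z);
    mat dc = dh % (1.0 - Z);
    mat dac = dc % (1.0 - C % C);
    mat dr = dac % HPC;
    mat dar = dr % R % (1.0 - R);
    mat dhpc = dac % R;
    dG.submat(t * B, 0, t * B + B - 1, H - 1) += daz;
    dG.submat(t * B, H, t * B + B - 1, 2 * H - 1) += dar;
    dG.submat(t * B, 2 * H, t * B + B - 1, 3 * H - 1) += dac;
    dUz += hprev.t() * daz;
    dUr += hprev.t() * dar;
    dUc += hprev.t() * dhpc;
    dh = dh % Z + daz * Uz.t() + dar * Ur.t() + dhpc * Uc.t();
  }
  dU.cols(0, H - 1) += dUz;
  dU.cols(H, 2 * H - 1) += dUr;
  dU.cols(2 * H, 3 * H - 1) += dUc;
}

// [[Rcpp::export]]
Rcpp::List cpp_bigru_fw(const arma::cube& X,
                        const arma::mat& Wf, const arma::mat& Uf, const arma::rowvec& bf,
                        const arma::mat& Wb, const arma::mat& Ub, const arma::rowvec& bb) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices, H = Uf.n_rows;
  mat Xflat = flatten_tm(X);
  mat Gf = Xflat * Wf; Gf.each_row() += bf;
  mat Gb = Xflat * Wb; Gb.each_row() += bb;
  cube Y(L, 2 * H, B);
  GruCache cf, cb;
  gru_dir_fw(Gf, Uf, L, B, H, false, Y, 0, cf);
  gru_dir_fw(Gb, Ub, L, B, H, true, Y, H, cb);
  return Rcpp::List::create(
    Rcpp::Named("Y") = Y,
    Rcpp::Named("cache") = Rcpp::List::create(
      Rcpp::Named("fZ") = cf.Z, Rcpp::Named("fR") = cf.R, Rcpp::Named("fC") = cf.C,
      Rcpp::Named("fHPC") = cf.HPC, Rcpp::Named("fH") = cf.H,
      Rcpp::Named("bZ") = cb.Z, Rcpp::Named("bR") = cb.R, Rcpp::Named("bC") = cb.C,
      Rcpp::Named("bHPC") = cb.HPC, Rcpp::Named("bH") = cb.H));
}

// [[Rcpp::export]]
Rcpp::List cpp_bigru_bw(const arma::cube& X,
                        const arma::mat& Wf, const arma::mat& Uf,
                        const arma::mat& Wb, const arma::mat& Ub,
                        const Rcpp::List& cache, const arma::cube& dY) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices, H = Uf.n_rows;
  mat Xflat = flatten_tm(X);
  GruCache cf, cb;
  cf.Z = Rcpp::as<cube>(cache["fZ"]); cf.R = Rcpp::as<cube>(cache["fR"]);
  cf.C = Rcpp::as<cube>(cache["fC"]); cf.HPC = Rcpp::as<cube>(cache["fHPC"]);
  cf.H = Rcpp::as<cube>(cache["fH"]);
  cb.Z = Rcpp::as<cube>(cache["bZ"]); cb.R = Rcpp::as<cube>(cache["bR"]);
  cb.C = Rcpp::as<cube>(cache["bC"]); cb.HPC = Rcpp::as<cube>(cache["bHPC"]);
  cb.H = Rcpp::as<cube>(cache["bH"]);

  mat dGf(L * B, 3 * H, fill::zeros), dGb(L * B, 3 * H, fill::zeros);
  mat dUf(H, 3 * H, fill::zeros), dUb(H, 3 * H, fill::zeros);
  gru_dir_bw(Uf, L, B, H, false, dY, 0, cf, dGf, dUf);
  gru_dir_bw(Ub, L, B, H, true, dY, H, cb, dGb, dUb);

  mat dWf = Xflat.t() * dGf;
  mat dWb = Xflat.t() * dGb;
  rowvec dbf = sum(dGf, 0);
  rowvec dbb = sum(dGb, 0);
  mat dXflat = dGf * Wf.t() + dGb * Wb.t();
  cube dX = unflatten_tm(dXflat, L, Cin, B);
  return Rcpp::List::create(
    Rcpp::Named("dX") = dX,
    Rcpp::Named("dWf") = dWf, Rcpp::Named("dUf") = dUf, Rcpp::Named("dbf") = dbf,
    Rcpp::Named("dWb") = dWb, Rcpp::Named("dUb") = dUb, Rcpp::Named("dbb") = dbb);
}

// ---------------------------------------------- semi-global alignment
//
// Read global, reference local (free reference flanks), unit
// mismatch/gap costs. Traceback tie-break on equal cost:
// match > mismatch > deletion (ref base skipped) > insertion (read
// base inserted). Returns M, U, I, D and the aligned reference span.

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_align_counts(const std::string& read,
                                     const std::string& ref) {
  const int n = read.size(), m = ref.size();
  if (n == 0 || m == 0)
    Rcpp::stop("both sequences must be non-empty");
  if ((double)(n + 1) * (double)(m + 1) > 8e7)
    Rcpp::stop("sequences too long for dense alignment");
  imat dp(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) dp(0, j) = 0;   // free reference prefix
  for (int i = 1; i <= n; ++i) {
    dp(i, 0) = i;
    for (int j = 1; j <= m; ++j) {
      int diag = dp(i - 1, j - 1) + (read[i - 1] == ref[j - 1] ? 0 : 1);
      int del = dp(i, j - 1) + 1;   // consume ref base
      int ins = dp(i - 1, j) + 1;   // consume read base
      dp(i, j) = std::min(diag, std::min(del, ins));
    }
  }
  int jend = 0, best = dp(n, 0);
  for (int j = 1; j <= m; ++j)
    if (dp(n, j) < best) { best = dp(n, j); jend = j; }

  int i = n, j = jend, M = 0, U = 0, I = 0, D = 0;
  while (i > 0) {
    if (j > 0 && read[i - 1] == ref[j - 1] && dp(i - 1, j - 1) == dp(i, j)) {
      ++M; --i; --j;
    } else if (j > 0 && dp(i - 1, j - 1) + 1 == dp(i, j)) {
      ++U; --i; --j;
    } else if (j > 0 && dp(i, j - 1) + 1 == dp(i, j)) {
      ++D; --j;
    } else {
      ++I; --i;
    }
  }
  return Rcpp::IntegerVector::create(
    Rcpp::Named("M") = M, Rcpp::Named("U") = U,
    Rcpp::Named("I") = I, Rcpp::Named("D") = D,
    Rcpp::Named("ref_start") = j, Rcpp::Named("ref_end") = jend);
}
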