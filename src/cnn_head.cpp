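// Fused forward/backward pass of the 1-D convolutional decoder head.
//
// A batch of b node embeddings of length `len` is stored as a (b*len) x c
// column-major matrix with row r <-> (node i, position p), node varying
// fastest (r = (p-1)*b + i). With that layout, shifting every node's signal
// by one position is a block row-shift, so same-padding kernel-3 convolution
// is one gemm against an explicit patch matrix, and flattening to the fully
// connected input is a layout-preserving reshape.
//
// Computation runs in single precision — the standard training precision for
// this kind of model — while parameters, gradients and the optimizer state
// stay in double on the R side (mixed precision with double master weights).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.1f;
static const double CLIP_EPS = 1e-7;

// kmat is (3*cin) x cout, rows tap-major (tap 1 = position p-1).
// build_patches materializes the nr x (3*cin) patch matrix P with the three
// shifted signal blocks side by side, so convolution is z = P kmat and the
// backward pass reuses P directly.
static fmat build_patches(const fmat& m, const uword b) {
  const uword nr = m.n_rows, c = m.n_cols;
  fmat p(nr, 3 * c, fill::zeros);
  p.submat(b, 0, nr - 1, c - 1) = m.rows(0, nr - 1 - b);         // tap at p-1
  p.cols(c, 2 * c - 1) = m;
  p.submat(0, 2 * c, nr - 1 - b, 3 * c - 1) = m.rows(b, nr - 1); // tap at p+1
  return p;
}

struct BlockCache {
  fmat patches; // P, the shifted-input matrix of the block
  fmat xhat;    // normalized pre-activation
  frowvec inv;  // 1/sqrt(var + eps)
  fmat mask;    // ReLU mask (0/1)
};

// per-channel batch normalization; training mode computes biased batch
// statistics (mean and variance in one pass) and updates the running stats
static fmat bn_fwd(fmat&& z, const frowvec& gamma, const frowvec& beta,
                   frowvec& run_mean, frowvec& run_var, bool training,
                   fmat& xhat_out, frowvec& inv_out) {
  if (training) {
    frowvec mu = mean(z, 0);
    frowvec v = mean(square(z), 0) - square(mu);
    v.transform([](float x) { return x > 0.0f ? x : 0.0f; }); // fp round-off
    inv_out = 1.0f / sqrt(v + BN_EPS);
    z.each_row() -= mu;
    z.each_row() %= inv_out;
    xhat_out = std::move(z);
    run_mean = (1.0f - BN_MOM) * run_mean + BN_MOM * mu;
    run_var = (1.0f - BN_MOM) * run_var + BN_MOM * v;
  } else {
    inv_out = 1.0f / sqrt(run_var + BN_EPS);
    z.each_row() -= run_mean;
    z.each_row() %= inv_out;
    xhat_out = std::move(z);
  }
  fmat y = xhat_out;
  y.each_row() %= gamma;
  y.each_row() += beta;
  return y;
}

static std::vector<fmat> as_fmats(const Rcpp::List& l) {
  std::vector<fmat> out;
  for (R_xlen_t i = 0; i < l.size(); ++i) {
    out.push_back(conv_to<fmat>::from(Rcpp::as<mat>(l[i])));
  }
  return out;
}

static std::vector<frowvec> as_frowvecs(const Rcpp::List& l) {
  std::vector<frowvec> out;
  for (R_xlen_t i = 0; i < l.size(); ++i) {
    out.push_back(conv_to<frowvec>::from(Rcpp::as<rowvec>(l[i])));
  }
  return out;
}

// forward through the conv blocks; when training, `caches` collects what the
// backward pass needs
static fmat blocks_forward(const fmat& emb, const std::vector<fmat>& kernels,
                           const std::vector<frowvec>& gamma,
                           const std::vector<frowvec>& beta,
                           std::vector<frowvec>& run_mean,
                           std::vector<frowvec>& run_var,
                           bool training, std::vector<BlockCache>* caches) {
  const uword b = emb.n_rows, len = emb.n_cols;
  fmat m(emb.memptr(), b * len, 1); // column-major copy-reshape
  for (size_t blk = 0; blk < kernels.size(); ++blk) {
    fmat p = build_patches(m, b);
    fmat z = p * kernels[blk];
    fmat xhat;
    frowvec inv;
    fmat y = bn_fwd(std::move(z), gamma[blk], beta[blk], run_mean[blk],
                    run_var[blk], training, xhat, inv);
    if (caches) {
      fmat mask = conv_to<fmat>::from(y > 0.0f);
      y %= mask;
      BlockCache c;
      c.patches = std::move(p);
      c.xhat = std::move(xhat);
      c.inv = inv;
      c.mask = std::move(mask);
      (*caches)[blk] = std::move(c);
    } else {
      y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    }
    m = std::move(y);
  }
  return m; // (b*len) x c_last
}

static fmat softmax_fc(const fmat& flat, const fmat& fc_w, const frowvec& fc_b) {
  fmat logits = flat * fc_w;
  logits.each_row() += fc_b;
  fmat p = exp(logits.each_col() - max(logits, 1));
  p.each_col() /= sum(p, 1);
  return p;
}

// [[Rcpp::export(name = ".cpp_head_infer")]]
arma::mat cpp_head_infer(const arma::mat& emb, const Rcpp::List& kernels,
                         const Rcpp::List& gamma, const Rcpp::List& beta,
                         const Rcpp::List& run_mean, const Rcpp::List& run_var,
                         const arma::mat& fc_w, const arma::vec& fc_b) {
  std::vector<fmat> K = as_fmats(kernels);
  std::vector<frowvec> g = as_frowvecs(gamma), be = as_frowvecs(beta);
  std::vector<frowvec> rm = as_frowvecs(run_mean), rv = as_frowvecs(run_var);
  const uword b = emb.n_rows;
  fmat last = blocks_forward(conv_to<fmat>::from(emb), K, g, be, rm, rv,
                             false, nullptr);
  fmat flat(last.memptr(), b, last.n_elem / b); // layout-preserving reshape
  fmat p = softmax_fc(flat, conv_to<fmat>::from(fc_w),
                      conv_to<frowvec>::from(fc_b.t()));
  return conv_to<mat>::from(p);
}

// one fused training step of the head on the labelled batch: forward with
// batch statistics and dropout, softmax cross-entropy gradient, backward to
// all head parameters and to the embedding. The dropout mask (already scaled
// by 1/keep) is drawn in R so reproducibility is governed by R's RNG.
// [[Rcpp::export(name = ".cpp_head_train_step")]]
Rcpp::List cpp_head_train_step(const arma::mat& emb, const Rcpp::List& kernels,
                               const Rcpp::List& gamma, const Rcpp::List& beta,
                               const Rcpp::List& run_mean, const Rcpp::List& run_var,
                               const arma::mat& fc_w, const arma::vec& fc_b,
                               const arma::vec& y, const arma::mat& dropout_mask,
                               bool use_dropout) {
  std::vector<fmat> K = as_fmats(kernels);
  std::vector<frowvec> g = as_frowvecs(gamma), be = as_frowvecs(beta);
  std::vector<frowvec> rm = as_frowvecs(run_mean), rv = as_frowvecs(run_var);
  const uword b = emb.n_rows, len = emb.n_cols;
  const size_t nblk = K.size();
  const fvec yf = conv_to<fvec>::from(y);

  std::vector<BlockCache> caches(nblk);
  fmat last = blocks_forward(conv_to<fmat>::from(emb), K, g, be, rm, rv,
                             true, &caches);
  fmat flat(last.memptr(), b, last.n_elem / b);
  fmat dmaskf;
  if (use_dropout) {
    dmaskf = conv_to<fmat>::from(dropout_mask);
    flat %= dmaskf;
  }
  fmat p = softmax_fc(flat, conv_to<fmat>::from(fc_w),
                      conv_to<frowvec>::from(fc_b.t()));

  // loss in double on the clipped positive-class probability
  vec p1 = clamp(conv_to<vec>::from(p.col(1)), CLIP_EPS, 1.0 - CLIP_EPS);
  double loss = mean(-y % log(p1) - (1.0 - y) % log(1.0 - p1));

  // softmax cross-entropy gradient, mean over the batch
  fmat dlogits = p;
  dlogits.col(0) -= (1.0f - yf);
  dlogits.col(1) -= yf;
  dlogits /= static_cast<float>(b);

  fmat dfc_w = flat.t() * dlogits;
  frowvec dfc_b = sum(dlogits, 0);
  fmat dflat = dlogits * conv_to<fmat>::from(fc_w).t();
  if (use_dropout) dflat %= dmaskf;
  fmat dm(dflat.memptr(), b * len, dflat.n_elem / (b * len)); // reshape back

  Rcpp::List dK(nblk), dgamma(nblk), dbeta(nblk);
  for (int blk = static_cast<int>(nblk) - 1; blk >= 0; --blk) {
    const BlockCache& c = caches[blk];
    const float n_rows = static_cast<float>(dm.n_rows);
    dm %= c.mask; // ReLU backward
    frowvec dgam = sum(dm % c.xhat, 0);
    frowvec dbet = sum(dm, 0);
    dgamma[blk] = Rcpp::wrap(conv_to<rowvec>::from(dgam));
    dbeta[blk] = Rcpp::wrap(conv_to<rowvec>::from(dbet));
    // with dxhat = gamma * dy: mean(dxhat) = gamma * dbeta / n and
    // mean(dxhat * xhat) = gamma * dgamma / n, so no extra reduction passes
    frowvec m1 = g[blk] % dbet / n_rows;
    frowvec m2 = g[blk] % dgam / n_rows;
    dm.each_row() %= g[blk];
    dm.each_row() -= m1;
    dm -= c.xhat.each_row() % m2;
    dm.each_row() %= c.inv; // now dz

    const uword cin = c.patches.n_cols / 3, nr = c.patches.n_rows;
    dK[blk] = Rcpp::wrap(conv_to<mat>::from(fmat(c.patches.t() * dm)));
    // gradient w.r.t. the block input: un-shift the patch gradient blocks
    fmat dp = dm * K[blk].t(); // nr x 3cin
    fmat dprev = dp.cols(cin, 2 * cin - 1);
    dprev.rows(0, nr - 1 - b) += dp.submat(b, 0, nr - 1, cin - 1);
    dprev.rows(b, nr - 1) += dp.submat(0, 2 * cin, nr - 1 - b, 3 * cin - 1);
    dm = std::move(dprev); // at blk 0 this is the gradient w.r.t. the embedding
  }

  Rcpp::List new_rm(nblk), new_rv(nblk);
  for (size_t i = 0; i < nblk; ++i) {
    new_rm[i] = Rcpp::wrap(conv_to<rowvec>::from(rm[i]));
    new_rv[i] = Rcpp::wrap(conv_to<rowvec>::from(rv[i]));
  }

  return Rcpp::List::create(
    Rcpp::Named("probs") = conv_to<mat>::from(p),
    Rcpp::Named("loss") = loss,
    Rcpp::Named("dkernels") = dK,
    Rcpp::Named("dgamma") = dgamma,
    Rcpp::Named("dbeta") = dbeta,
    Rcpp::Named("dfc_w") = conv_to<mat>::from(dfc_w),
    Rcpp::Named("dfc_b") = conv_to<rowvec>::from(dfc_b),
    Rcpp::Named("demb") = conv_to<mat>::from(fmat(dm.memptr(), b, len)),
    Rcpp::Named("run_mean") = new_rm,
    Rcpp::Named("run_var") = new_rv
  );
}
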