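// Two-layer additive bidirectional LSTM regressor: batched forward pass and
// full backpropagation through time.  The backward pass returns both
// parameter gradients (training) and input gradients (saliency); the two
// share one cache so the saliency gradient is the exact derivative of the
// scalar the forward pass computes.
//
// Layout conventions:
//   - a batch of sequences is a cube X of dimensions (d, B, T): X.slice(t)
//     is the d x B matrix of inputs at timestep t;
//   - one direction's parameters are W (4h x d), U (4h x h), b (4h),
//     h0 (h), c0 (h); gate order within the 4h axis is input, forget,
//     cell-candidate, output;
//   - the learnable initial hidden and cell states h0/c0 are broadcast over
//     the batch and receive summed gradients.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct DirParams {
  mat W, U;
  vec b, h0, c0;
  uword h() const { return U.n_cols; }
};

DirParams dir_from_list(const Rcpp::List& l) {
  DirParams p;
  p.W = Rcpp::as<mat>(l["W"]);
  p.U = Rcpp::as<mat>(l["U"]);
  p.b = Rcpp::as<vec>(l["b"]);
  p.h0 = Rcpp::as<vec>(l["h0"]);
  p.c0 = Rcpp::as<vec>(l["c0"]);
  return p;
}

// gate caches for one direction over a whole sequence
struct DirCache {
  cube I, F, G, O, C, TC;  // each (h, B, T); C is post-update cell state
};

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

cube flip_time(const cube& X) {
  cube Y(size(X));
  const uword T = X.n_slices;
  for (uword t = 0; t < T; ++t) Y.slice(t) = X.slice(T - 1 - t);
  return Y;
}

// forward one direction in natural slice order; caller flips for reverse.
// The input projection W * X over all timesteps is hoisted into a single
// GEMM; the recurrence loop only carries the h-sized state updates.
cube dir_forward(const DirParams& p, const cube& X, DirCache* cache) {
  const uword d = X.n_rows, B = X.n_cols, T = X.n_slices, h = p.h();
  if (p.W.n_cols != d) Rcpp::stop("input dimension mismatch: expected %d, got %d", p.W.n_cols, d);
  cube H(h, B, T);
  if (cache) {
    cache->I.set_size(h, B, T); cache->F.set_size(h, B, T);
    cache->G.set_size(h, B, T); cache->O.set_size(h, B, T);
    cache->C.set_size(h, B, T); cache->TC.set_size(h, B, T);
  }
  const mat Xall(const_cast<double*>(X.memptr()), d, B * T, false, true);
  mat Aall = p.W * Xall;  // (4h, B*T)
  mat hprev = repmat(p.h0, 1, B), cprev = repmat(p.c0, 1, B);
  for (uword t = 0; t < T; ++t) {
    mat a = Aall.cols(t * B, (t + 1) * B - 1) + p.U * hprev;
    a.each_col() += p.b;
    mat i = sigm(a.rows(0, h - 1));
    mat f = sigm(a.rows(h, 2 * h - 1));
    mat g = tanh(a.rows(2 * h, 3 * h - 1));
    mat o = sigm(a.rows(3 * h, 4 * h - 1));
    mat c = f % cprev + i % g;
    mat tc = tanh(c);
    H.slice(t) = o % tc;
    if (cache) {
      cache->I.slice(t) = i; cache->F.slice(t) = f;
      cache->G.slice(t) = g; cache->O.slice(t) = o;
      cache->C.slice(t) = c; cache->TC.slice(t) = tc;
    }
    hprev = H.slice(t);
    cprev = std::move(c);
  }
  return H;
}

struct DirGrads {
  mat dW, dU;
  vec db, dh0, dc0;
};

// backward one direction given dH (h,B,T) in the same slice order as forward.
cube dir_backward(const DirParams& p, const cube& X, const cube& H,
                  const DirCache& cc, const cube& dH, DirGrads& g) {
  const uword d = X.n_rows, B = X.n_cols, T = X.n_slices, h = p.h();
  g.dU = zeros<mat>(size(p.U));
  g.db = zeros<vec>(4 * h);
  cube dA(4 * h, B, T);  // gate pre-activation gradients, for one big GEMM
  mat dh_next = zeros<mat>(h, B), dc_next = zeros<mat>(h, B);
  for (uword tt = T; tt-- > 0;) {
    mat dh = dH.slice(tt) + dh_next;
    const mat& i = cc.I.slice(tt);
    const mat& f = cc.F.slice(tt);
    const mat& gg = cc.G.slice(tt);
    const mat& o = cc.O.slice(tt);
    const mat& tc = cc.TC.slice(tt);
    mat dc = dc_next + dh % o % (1.0 - tc % tc);
    mat cprev = (tt == 0) ? repmat(p.c0, 1, B) : cc.C.slice(tt - 1);
    mat hprev = (tt == 0) ? repmat(p.h0, 1, B) : H.slice(tt - 1);
    mat da = dA.slice(tt);
    da.rows(0, h - 1)         = (dc % gg) % i % (1.0 - i);
    da.rows(h, 2 * h - 1)     = (dc % cprev) % f % (1.0 - f);
    da.rows(2 * h, 3 * h - 1) = (dc % i) % (1.0 - gg % gg);
    da.rows(3 * h, 4 * h - 1) = (dh % tc) % o % (1.0 - o);
    dA.slice(tt) = da;
    g.dU += da * hprev.t();
    g.db += sum(da, 1);
    dh_next = p.U.t() * da;
    dc_next = dc % f;
  }
  g.dh0 = sum(dh_next, 1);
  g.dc0 = sum(dc_next, 1);
  const mat Xall(const_cast<double*>(X.memptr()), d, B * T, false, true);
  const mat dAall(const_cast<double*>(dA.memptr()), 4 * h, B * T, false, true);
  g.dW = dAall * Xall.t();
  cube dX(d, B, T);
  mat dXall(dX.memptr(), d, B * T, false, true);
  dXall = p.W.t() * dAall;
  return dX;
}

Rcpp::List grads_to_list(const DirGrads& g) {
  return Rcpp::List::create(Rcpp::Named("W") = g.dW, Rcpp::Named("U") = g.dU,
                            Rcpp::Named("b") = g.db, Rcpp::Named("h0") = g.dh0,
                            Rcpp::Named("c0") = g.dc0);
}

struct ModelParams {
  DirParams l1f, l1b, l2f, l2b;
  vec hw;
  double hb;
};

ModelParams model_from_list(const Rcpp::List& params) {
  ModelParams m;
  m.l1f = dir_from_list(params["l1f"]);
  m.l1b = dir_from_list(params["l1b"]);
  m.l2f = dir_from_list(params["l2f"]);
  m.l2b = dir_from_list(params["l2b"]);
  Rcpp::List head = params["head"];
  m.hw = Rcpp::as<vec>(head["w"]);
  m.hb = Rcpp::as<double>(head["b"]);
  return m;
}

rowvec forward_outputs(const ModelParams& m, const cube& X) {
  const uword B = X.n_cols, T = X.n_slices;
  cube Xr = flip_time(X);
  cube H1 = dir_forward(m.l1f, X, nullptr) + flip_time(dir_forward(m.l1b, Xr, nullptr));
  cube H1r = flip_time(H1);
  cube H2 = dir_forward(m.l2f, H1, nullptr) + flip_time(dir_forward(m.l2b, H1r, nullptr));
  mat v = zeros<mat>(m.l2f.h(), B);
  for (uword t = 0; t < T; ++t) v += H2.slice(t);
  v /= static_cast<double>(T);
  return m.hw.t() * v + m.hb;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector cpp_bilstm_forward(Rcpp::List params, arma::cube X) {
  ModelParams m = model_from_list(params);
  rowvec out = forward_outputs(m, X);
  return Rcpp::NumericVector(out.begin(), out.end());
}

namespace {

// shared forward + backward machinery.  If `mse_target` is non-null the
// objective is the batch MSE against it and dout_in is ignored; otherwise
// dout_in is the gradient of the objective w.r.t. each sequence's output.
Rcpp::List backward_impl(const ModelParams& m, const cube& X, vec dout,
                         const vec* mse_target, bool need_dx) {
  const uword B = X.n_cols, T = X.n_slices, h = m.l2f.h();
  if (!mse_target && dout.n_elem != B) Rcpp::stop("dout length must equal batch size");

  cube Xr = flip_time(X);
  DirCache c1f, c1b, c2f, c2b;
  cube H1f = dir_forward(m.l1f, X, &c1f);
  cube H1br = dir_forward(m.l1b, Xr, &c1b);  // in reversed order
  cube H1 = H1f + flip_time(H1br);
  cube H1r = flip_time(H1);
  cube H2f = dir_forward(m.l2f, H1, &c2f);
  cube H2br = dir_forward(m.l2b, H1r, &c2b);
  cube H2 = H2f + flip_time(H2br);

  mat v = zeros<mat>(h, B);
  for (uword t = 0; t < T; ++t) v += H2.slice(t);
  v /= static_cast<double>(T);
  rowvec out = m.hw.t() * v + m.hb;

  double loss = NA_REAL;
  if (mse_target) {
    vec resid = out.t() - *mse_target;
    loss = dot(resid, resid) / static_cast<double>(B);
    dout = 2.0 * resid / static_cast<double>(B);
  }

  // head gradients
  vec dw = v * dout;
  double db = accu(dout);
  mat dv = m.hw * dout.t();  // (h, B)

  cube dH2(h, B, T);
  mat dv_over_T = dv / static_cast<double>(T);
  for (uword t = 0; t < T; ++t) dH2.slice(t) = dv_over_T;

  DirGrads g2f, g2b, g1f, g1b;
  cube dH1 = dir_backward(m.l2f, H1, H2f, c2f, dH2, g2f);
  dH1 += flip_time(dir_backward(m.l2b, H1r, H2br, c2b, flip_time(dH2), g2b));
  cube dX = dir_backward(m.l1f, X, H1f, c1f, dH1, g1f);
  dX += flip_time(dir_backward(m.l1b, Xr, H1br, c1b, flip_time(dH1), g1b));

  Rcpp::List res = Rcpp::List::create(
      Rcpp::Named("out") = Rcpp::NumericVector(out.begin(), out.end()),
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("l1f") = grads_to_list(g1f),
          Rcpp::Named("l1b") = grads_to_list(g1b),
          Rcpp::Named("l2f") = grads_to_list(g2f),
          Rcpp::Named("l2b") = grads_to_list(g2b),
          Rcpp::Named("head") = Rcpp::List::create(Rcpp::Named("w") = dw,
                                                   Rcpp::Named("b") = db)));
  if (need_dx) res["dX"] = dX;
  if (mse_target) res["loss"] = loss;
  return res;
}

}  // namespace

// Backward pass: returns outputs, input gradient dX (d,B,T) of
// sum(dout * out), and parameter gradients mirroring the params structure.
// [[Rcpp::export]]
Rcpp::List cpp_bilstm_backward(Rcpp::List params, arma::cube X, arma::vec dout) {
  ModelParams m = model_from_list(params);
  return backward_impl(m, X, dout, nullptr, true);
}

// One MSE training step's worth of gradients: the objective is
// mean((out - y)^2) over the batch; dX is skipped for speed.
// [[Rcpp::export]]
Rcpp::List cpp_bilstm_mse_grad(Rcpp::List params, arma::cube X, arma::vec y) {
  ModelParams m = model_from_list(params);
  if (y.n_elem != X.n_cols) Rcpp::stop("y length must equal batch size");
  return backward_impl(m, X, vec(), &y, false);
}

// Ensemble-averaged outputs for many ablated copies of one validation batch.
// `sets` holds 1-based region-index vectors; for each set the listed rows of
// X are zeroed and every member's forward pass is run.  Members are parsed
// once, which is what makes large resampling nulls affordable.
// Returns a (n_sets x B) matrix of member-averaged per-session outputs.
// [[Rcpp::export]]
arma::mat cpp_forward_ablate_sets(Rcpp::List members, arma::cube X, Rcpp::List sets) {
  const uword B = X.n_cols;
  std::vector<ModelParams> ms;
  ms.reserve(members.size());
  for (R_xlen_t i = 0; i < members.size(); ++i) {
    ms.push_back(model_from_list(members[i]));
  }
  mat out(sets.size(), B);
  for (R_xlen_t s = 0; s < sets.size(); ++s) {
    arma::uvec idx = Rcpp::as<arma::uvec>(sets[s]);
    cube Xa = X;
    for (uword j = 0; j < idx.n_elem; ++j) {
      if (idx[j] < 1 || idx[j] > X.n_rows) Rcpp::stop("region index out of range");
      Xa.row(idx[j] - 1).zeros();
    }
    rowvec acc(B, fill::zeros);
    for (const ModelParams& m : ms) acc += forward_outputs(m, Xa);
    out.row(s) = acc / static_cast<double>(ms.size());
  }
  return out;
}
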