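// Batched forward/backward pass of the transformer-encoder read classifier
// and the Adam update.  The reference (readable) implementations of each
// operation live in R/model.R; this file is the fused fast path used by
// training and inference.  Gradients are derived by hand for: embedding
// lookup (plain table and hash-embedding pool), scaled dot-product attention
// with additive -inf padding mask, post-norm residual blocks with layer
// normalization, masked mean / cls / concat sequence reduction, and
// interconnected multi-level linear heads with class-weighted cross-entropy.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double MASK_NEG = -1e30;

static arma::mat softmax_rows(const arma::mat &S) {
  arma::vec mx = arma::max(S, 1);
  arma::mat A = arma::exp(S.each_col() - mx);
  arma::vec sm = arma::sum(A, 1);
  A.each_col() /= sm;
  return A;
}

static void round_f32(arma::mat &X) {
  for (arma::uword i = 0; i < X.n_elem; ++i) X[i] = (double)(float)X[i];
}

// layer norm forward over the feature dimension; returns normalized output,
// fills xhat and invstd caches
static arma::mat ln_forward(const arma::mat &X, const arma::rowvec &g,
                            const arma::rowvec &b, double eps,
                            arma::mat &xhat, arma::vec &invstd) {
  arma::vec mu = arma::mean(X, 1);
  arma::mat xc = X.each_col() - mu;
  arma::vec var = arma::sum(arma::square(xc), 1) / (double)X.n_cols;
  invstd = 1.0 / arma::sqrt(var + eps);
  xhat = xc.each_col() % invstd;
  arma::mat out = xhat.each_row() % g;
  out.each_row() += b;
  return out;
}

// layer norm backward; accumulates dg, db, returns dX
static arma::mat ln_backward(const arma::mat &dY, const arma::mat &xhat,
                             const arma::vec &invstd, const arma::rowvec &g,
                             arma::rowvec &dg, arma::rowvec &db) {
  double d = (double)dY.n_cols;
  dg = arma::sum(dY % xhat, 0);
  db = arma::sum(dY, 0);
  arma::mat dxhat = dY.each_row() % g;
  arma::vec m1 = arma::sum(dxhat, 1) / d;
  arma::vec m2 = arma::sum(dxhat % xhat, 1) / d;
  arma::mat dX = dxhat.each_col() - m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= invstd;
  return dX;
}

struct BlockCache {
  arma::mat Ein, Q, K, V, Zc, Nn, H, xhat1, xhat2;
  arma::vec invstd1, invstd2;
  std::vector<arma::mat> A; // B*h attention matrices, index b*h + j
};

// [[Rcpp::export]]
List cpp_model_pass(List inputs, List params, List cfg, arma::mat P,
                    List labels, List wts, bool want_grad, List dropmasks) {
  const int h = as<int>(cfg["h"]);
  const int nb = as<int>(cfg["n_blocks"]);
  const int d = as<int>(cfg["d_model"]);
  const std::string reduction = as<std::string>(cfg["reduction"]);
  const double eps = as<double>(cfg["ln_eps"]);
  const bool rp = as<bool>(cfg["reduced_precision"]);
  const std::string emb_mode = as<std::string>(cfg["emb_mode"]); // table|hash
  const int dk = d / h;
  const double scale = std::sqrt((double)d);
  const double att_scale = 1.0 / std::sqrt((double)dk);
  const bool use_drop = dropmasks.size() > 0;

  IntegerMatrix maskM = inputs["mask"];
  const int B = maskM.nrow(), n = maskM.ncol();
  const int Bn = B * n;

  // ---- embedding + positional encoding -------------------------------
  arma::mat Ebig(Bn, d);
  arma::mat emb, pool, impw;
  IntegerMatrix idsM, impM;
  IntegerVector compV;
  int q = 0;
  if (emb_mode == "table") {
    emb = as<arma::mat>(params["emb"]);
    idsM = as<IntegerMatrix>(inputs["ids"]);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < n; ++t)
        Ebig.row(b * n + t) = emb.row(idsM(b, t)) * scale + P.row(t);
  } else {
    pool = as<arma::mat>(params["pool"]);
    impw = as<arma::mat>(params["impw"]);
    impM = as<IntegerMatrix>(inputs["imp"]);
    compV = as<IntegerVector>(inputs["comp"]); // dim B x n x q
    IntegerVector dim = compV.attr("dim");
    q = dim[2];
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < n; ++t) {
        arma::rowvec e(d, arma::fill::zeros);
        int slot = impM(b, t);
        for (int j = 0; j < q; ++j) {
          int c = compV[b + B * (t + n * j)];
          e += impw(slot, j) * pool.row(c);
        }
        Ebig.row(b * n + t) = e * scale + P.row(t);
      }
  }
  arma::mat drop_inp;
  if (use_drop && dropmasks.containsElementNamed("inp")) {
    drop_inp = as<arma::mat>(dropmasks["inp"]);
    Ebig %= drop_inp;
  }
  if (rp) round_f32(Ebig);

  // per-sample unmasked counts (for mean reduction and sanity)
  arma::vec cnt(B, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < n; ++t) cnt[b] += maskM(b, t);
  if (arma::any(cnt == 0)) stop("a sequence with all positions masked");

  // ---- encoder blocks -------------------------------------------------
  std::vector<BlockCache> cache(nb);
  arma::mat E = Ebig;
  std::vector<arma::mat> drop_att(nb), drop_mlp(nb);
  for (int i = 0; i < nb; ++i) {
    std::string si = std::to_string(i + 1);
    if (use_drop && dropmasks.containsElementNamed(("att" + si).c_str()))
      drop_att[i] = as<arma::mat>(dropmasks["att" + si]);
    if (use_drop && dropmasks.containsElementNamed(("mlp" + si).c_str()))
      drop_mlp[i] = as<arma::mat>(dropmasks["mlp" + si]);

    BlockCache &C = cache[i];
    C.Ein = E;
    arma::mat Wq = as<arma::mat>(params["Wq" + si]);
    arma::mat Wk = as<arma::mat>(params["Wk" + si]);
    arma::mat Wv = as<arma::mat>(params["Wv" + si]);
    arma::mat Wo = as<arma::mat>(params["Wo" + si]);
    arma::rowvec g1 = as<arma::rowvec>(params["ln1g" + si]);
    arma::rowvec b1 = as<arma::rowvec>(params["ln1b" + si]);
    arma::rowvec g2 = as<arma::rowvec>(params["ln2g" + si]);
    arma::rowvec b2 = as<arma::rowvec>(params["ln2b" + si]);
    arma::mat W1 = as<arma::mat>(params["W1" + si]);
    arma::rowvec bb1 = as<arma::rowvec>(params["bb1" + si]);
    arma::mat W2 = as<arma::mat>(params["W2" + si]);
    arma::rowvec bb2 = as<arma::rowvec>(params["bb2" + si]);

    C.Q = E * Wq; C.K = E * Wk; C.V = E * Wv;
    C.Zc.set_size(Bn, d);
    C.A.assign((size_t)B * h, arma::mat());
    for (int b = 0; b < B; ++b) {
      int r0 = b * n;
      for (int j = 0; j < h; ++j) {
        int c0 = j * dk;
        arma::mat Qh = C.Q.submat(r0, c0, r0 + n - 1, c0 + dk - 1);
        arma::mat Kh = C.K.submat(r0, c0, r0 + n - 1, c0 + dk - 1);
        arma::mat S = (Qh * Kh.t()) * att_scale;
        for (int t = 0; t < n; ++t)
          if (maskM(b, t) == 0) S.col(t).fill(MASK_NEG);
        arma::mat A = softmax_rows(S);
        C.A[(size_t)b * h + j] = A;
        C.Zc.submat(r0, c0, r0 + n - 1, c0 + dk - 1) =
          A * C.V.submat(r0, c0, r0 + n - 1, c0 + dk - 1);
      }
    }
    arma::mat Z = C.Zc * Wo;
    if (drop_att[i].n_elem) Z %= drop_att[i];
    arma::mat Zr = Z + E;
    C.Nn = ln_forward(Zr, g1, b1, eps, C.xhat1, C.invstd1);
    arma::mat H0 = C.Nn * W1;
    H0.each_row() += bb1;
    C.H = H0;
    C.H.elem(arma::find(C.H < 0)).zeros();
    arma::mat Mo = C.H * W2;
    Mo.each_row() += bb2;
    if (drop_mlp[i].n_elem) Mo %= drop_mlp[i];
    arma::mat O1 = Mo + C.Nn;
    E = ln_forward(O1, g2, b2, eps, C.xhat2, C.invstd2);
    if (rp) round_f32(E);
  }
  arma::mat Eout = E;

  // ---- reduction ------------------------------------------------------
  arma::mat X(B, d, arma::fill::zeros);
  arma::mat Wred;
  if (reduction == "mean") {
    for (int b = 0; b < B; ++b) {
      arma::rowvec s(d, arma::fill::zeros);
      for (int t = 0; t < n; ++t)
        if (maskM(b, t)) s += Eout.row(b * n + t);
      X.row(b) = s / cnt[b];
    }
  } else if (reduction == "cls") {
    for (int b = 0; b < B; ++b) X.row(b) = Eout.row(b * n);
  } else { // concat
    Wred = as<arma::mat>(params["Wred"]); // (n*d) x d
    for (int b = 0; b < B; ++b) {
      arma::rowvec v(n * d);
      for (int t = 0; t < n; ++t)
        v.subvec(t * d, t * d + d - 1) = Eout.row(b * n + t);
      X.row(b) = v * Wred;
    }
  }

  // ---- heads ----------------------------------------------------------
  IntegerVector Ms = cfg["levels"]; // class count per level, coarse -> fine
  const int L = Ms.size();
  std::vector<arma::mat> Y(L), Tm(L);
  for (int l = 0; l < L; ++l) {
    std::string sl = std::to_string(l + 1);
    arma::mat HW = as<arma::mat>(params["HW" + sl]);
    arma::rowvec Hb = as<arma::rowvec>(params["Hb" + sl]);
    Y[l] = X * HW;
    Y[l].each_row() += Hb;
    if (l > 0) {
      Tm[l] = as<arma::mat>(params["T" + std::to_string(l)]); // M_l x M_{l-1}
      Y[l] += Y[l - 1] * Tm[l].t();
    }
  }

  List scores(L);
  for (int l = 0; l < L; ++l) scores[l] = wrap(Y[l]);

  // ---- loss -----------------------------------------------------------
  double loss = NA_REAL;
  std::vector<arma::mat> dCE(L);
  bool have_labels = labels.size() > 0;
  if (have_labels) {
    loss = 0.0;
    for (int l = 0; l < L; ++l) {
      IntegerVector y = labels[l]; // 1-based
      arma::vec w;
      if (wts.size() > l && !Rf_isNull(wts[l])) w = as<arma::vec>(wts[l]);
      else w = arma::vec(Ms[l], arma::fill::ones);
      arma::vec mx = arma::max(Y[l], 1);
      arma::mat Ex = arma::exp(Y[l].each_col() - mx);
      arma::vec sm = arma::sum(Ex, 1);
      arma::vec lse = mx + arma::log(sm);
      if (want_grad) dCE[l] = Ex.each_col() / sm; // softmax probs, reused
      for (int b = 0; b < B; ++b) {
        int yi = y[b] - 1;
        loss += w[yi] * (lse[b] - Y[l](b, yi));
        if (want_grad) {
          dCE[l].row(b) *= w[yi] / (double)B;
          dCE[l](b, yi) -= w[yi] / (double)B;
        }
      }
    }
    loss /= (double)B;
  }

  if (!want_grad)
    return List::create(_["loss"] = loss, _["scores"] = scores);

  if (!have_labels) stop("gradients require labels");

  // ---- backward: heads ------------------------------------------------
  List grads;
  std::vector<arma::mat> dY(L);
  for (int l = L - 1; l >= 0; --l) {
    dY[l] = dCE[l];
    if (l < L - 1) dY[l] += dY[l + 1] * Tm[l + 1];
  }
  arma::mat dX(B, d, arma::fill::zeros);
  for (int l = 0; l < L; ++l) {
    std::string sl = std::to_string(l + 1);
    arma::mat HW = as<arma::mat>(params["HW" + sl]);
    grads["HW" + sl] = wrap(arma::mat(X.t() * dY[l]));
    grads["Hb" + sl] = wrap(arma::rowvec(arma::sum(dY[l], 0)));
    if (l > 0)
      grads["T" + std::to_string(l)] = wrap(arma::mat(dY[l].t() * Y[l - 1]));
    dX += dY[l] * HW.t();
  }

  // ---- backward: reduction -------------------------------------------
  arma::mat dE(Bn, d, arma::fill::zeros);
  if (reduction == "mean") {
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < n; ++t)
        if (maskM(b, t)) dE.row(b * n + t) = dX.row(b) / cnt[b];
  } else if (reduction == "cls") {
    for (int b = 0; b < B; ++b) dE.row(b * n) = dX.row(b);
  } else {
    arma::mat dWred(n * d, d, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      arma::rowvec v(n * d);
      for (int t = 0; t < n; ++t)
        v.subvec(t * d, t * d + d - 1) = Eout.row(b * n + t);
      dWred += v.t() * dX.row(b);
      arma::rowvec dv = dX.row(b) * Wred.t();
      for (int t = 0; t < n; ++t)
        dE.row(b * n + t) += dv.subvec(t * d, t * d + d - 1);
    }
    grads["Wred"] = wrap(dWred);
  }

  // ---- backward: encoder blocks --------------------------------------
  for (int i = nb - 1; i >= 0; --i) {
    std::string si = std::to_string(i + 1);
    BlockCache &C = cache[i];
    arma::mat Wo = as<arma::mat>(params["Wo" + si]);
    arma::rowvec g1 = as<arma::rowvec>(params["ln1g" + si]);
    arma::rowvec g2 = as<arma::rowvec>(params["ln2g" + si]);
    arma::mat W1 = as<arma::mat>(params["W1" + si]);
    arma::mat W2 = as<arma::mat>(params["W2" + si]);
    arma::mat Wq = as<arma::mat>(params["Wq" + si]);
    arma::mat Wk = as<arma::mat>(params["Wk" + si]);
    arma::mat Wv = as<arma::mat>(params["Wv" + si]);

    arma::rowvec dg2, db2;
    arma::mat dO1 = ln_backward(dE, C.xhat2, C.invstd2, g2, dg2, db2);
    grads["ln2g" + si] = wrap(dg2);
    grads["ln2b" + si] = wrap(db2);

    arma::mat dMo = dO1;
    if (drop_mlp[i].n_elem) dMo %= drop_mlp[i];
    arma::mat dNn = dO1; // residual branch
    grads["W2" + si] = wrap(arma::mat(C.H.t() * dMo));
    grads["bb2" + si] = wrap(arma::rowvec(arma::sum(dMo, 0)));
    arma::mat dH = dMo * W2.t();
    dH.elem(arma::find(C.H <= 0)).zeros();
    grads["W1" + si] = wrap(arma::mat(C.Nn.t() * dH));
    grads["bb1" + si] = wrap(arma::rowvec(arma::sum(dH, 0)));
    dNn += dH * W1.t();

    arma::rowvec dg1, db1;
    arma::mat dZr = ln_backward(dNn, C.xhat1, C.invstd1, g1, dg1, db1);
    grads["ln1g" + si] = wrap(dg1);
    grads["ln1b" + si] = wrap(db1);

    arma::mat dZ = dZr;
    if (drop_att[i].n_elem) dZ %= drop_att[i];
    grads["Wo" + si] = wrap(arma::mat(C.Zc.t() * dZ));
    arma::mat dZc = dZ * Wo.t();

    arma::mat dQ(Bn, d, arma::fill::zeros), dK(Bn, d, arma::fill::zeros),
              dV(Bn, d, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      int r0 = b * n;
      for (int j = 0; j < h; ++j) {
        int c0 = j * dk;
        const arma::mat &A = C.A[(size_t)b * h + j];
        arma::mat da = dZc.submat(r0, c0, r0 + n - 1, c0 + dk - 1);
        arma::mat Vh = C.V.submat(r0, c0, r0 + n - 1, c0 + dk - 1);
        arma::mat dA = da * Vh.t();
        dV.submat(r0, c0, r0 + n - 1, c0 + dk - 1) = A.t() * da;
        arma::vec rs = arma::sum(dA % A, 1);
        arma::mat dS = A % (dA.each_col() - rs);
        arma::mat Qh = C.Q.submat(r0, c0, r0 + n - 1, c0 + dk - 1);
        arma::mat Kh = C.K.submat(r0, c0, r0 + n - 1, c0 + dk - 1);
        dQ.submat(r0, c0, r0 + n - 1, c0 + dk - 1) = dS * Kh * att_scale;
        dK.submat(r0, c0, r0 + n - 1, c0 + dk - 1) = dS.t() * Qh * att_scale;
      }
    }
    grads["Wq" + si] = wrap(arma::mat(C.Ein.t() * dQ));
    grads["Wk" + si] = wrap(arma::mat(C.Ein.t() * dK));
    grads["Wv" + si] = wrap(arma::mat(C.Ein.t() * dV));
    dE = dZr + dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
  }

  // ---- backward: embedding -------------------------------------------
  if (drop_inp.n_elem) dE %= drop_inp;
  List touched;
  if (emb_mode == "table") {
    arma::mat dEmb(emb.n_rows, d, arma::fill::zeros);
    std::vector<char> seen(emb.n_rows, 0);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < n; ++t) {
        int id = idsM(b, t);
        dEmb.row(id) += dE.row(b * n + t) * scale;
        seen[id] = 1;
      }
    grads["emb"] = wrap(dEmb);
    std::vector<int> rows;
    for (size_t r = 0; r < seen.size(); ++r)
      if (seen[r]) rows.push_back((int)r + 1);
    touched["emb"] = wrap(rows);
  } else {
    arma::mat dPool(pool.n_rows, d, arma::fill::zeros);
    arma::mat dImpw(impw.n_rows, q, arma::fill::zeros);
    std::vector<char> seenp(pool.n_rows, 0), seeni(impw.n_rows, 0);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < n; ++t) {
        int slot = impM(b, t);
        arma::rowvec de = dE.row(b * n + t) * scale;
        for (int j = 0; j < q; ++j) {
          int c = compV[b + B * (t + n * j)];
          dPool.row(c) += impw(slot, j) * de;
          dImpw(slot, j) += arma::dot(pool.row(c), de);
          seenp[c] = 1;
        }
        seeni[slot] = 1;
      }
    grads["pool"] = wrap(dPool);
    grads["impw"] = wrap(dImpw);
    std::vector<int> rp_, ri_;
    for (size_t r = 0; r < seenp.size(); ++r) if (seenp[r]) rp_.push_back((int)r + 1);
    for (size_t r = 0; r < seeni.size(); ++r) if (seeni[r]) ri_.push_back((int)r + 1);
    touched["pool"] = wrap(rp_);
    touched["impw"] = wrap(ri_);
  }

  return List::create(_["loss"] = loss, _["scores"] = scores,
                      _["grads"] = grads, _["touched"] = touched);
}

// Adam update.  With `sparse` given (name -> 1-based row indices), only the
// listed rows of those parameters (and their moment estimates) are updated,
// mirroring SparseAdam semantics for embedding tables.
// [[Rcpp::export]]
List cpp_adam_step(List params, List grads, List m, List v, int t, double lr,
                   double beta1, double beta2, double eps,
                   Nullable<List> sparse) {
  CharacterVector names = grads.names();
  double bc1 = 1.0 - std::pow(beta1, (double)t);
  double bc2 = 1.0 - std::pow(beta2, (double)t);
  List sp;
  if (sparse.isNotNull()) sp = sparse.get();
  for (R_xlen_t i = 0; i < names.size(); ++i) {
    std::string nm = as<std::string>(names[i]);
    arma::mat g = as<arma::mat>(grads[nm]);
    arma::mat p = as<arma::mat>(params[nm]);
    arma::mat mm = as<arma::mat>(m[nm]);
    arma::mat vv = as<arma::mat>(v[nm]);
    if (sp.size() > 0 && sp.containsElementNamed(nm.c_str())) {
      IntegerVector rows = sp[nm];
      for (R_xlen_t r = 0; r < rows.size(); ++r) {
        int rr = rows[r] - 1;
        mm.row(rr) = beta1 * mm.row(rr) + (1 - beta1) * g.row(rr);
        vv.row(rr) = beta2 * vv.row(rr) + (1 - beta2) * arma::square(g.row(rr));
        p.row(rr) -= lr * (mm.row(rr) / bc1) /
                     (arma::sqrt(vv.row(rr) / bc2) + eps);
      }
    } else {
      mm = beta1 * mm + (1 - beta1) * g;
      vv = beta2 * vv + (1 - beta2) * arma::square(g);
      p -= lr * (mm / bc1) / (arma::sqrt(vv / bc2) + eps);
    }
    params[nm] = wrap(p);
    m[nm] = wrap(mm);
    v[nm] = wrap(vv);
  }
  return List::create(_["params"] = params, _["m"] = m, _["v"] = v);
}
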