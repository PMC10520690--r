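// Convolutional network for contact-map deconvolution.
//
// The architecture is fixed in shape (4 conv layers, max-pooling after the
// first three, 2 hidden dense layers, simplex output) but parameterised in
// width. All tensors are column-major; feature maps are arma::cube (H, W, C)
// and the flatten order is arma's vectorise() order (row index fastest).
// Convolutions use 3x3 (configurable k) kernels with "same" zero padding;
// pooling is 2x2 stride 2 with "valid" truncation of odd trailing rows/cols.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct NetCfg {
  int H, W, K, k;          // input rows, cols, output size, kernel size
  ivec ch;                 // 4 conv channel counts
  ivec dense;              // 2 hidden dense widths
  bool softmax_out;
};

NetCfg parse_cfg(const Rcpp::List& cfg) {
  NetCfg c;
  c.H = Rcpp::as<int>(cfg["H"]);
  c.W = Rcpp::as<int>(cfg["W"]);
  c.K = Rcpp::as<int>(cfg["K"]);
  c.k = Rcpp::as<int>(cfg["kernel"]);
  c.ch = Rcpp::as<ivec>(cfg["channels"]);
  c.dense = Rcpp::as<ivec>(cfg["dense"]);
  c.softmax_out = Rcpp::as<bool>(cfg["softmax"]);
  if (c.ch.n_elem != 4) Rcpp::stop("need 4 conv channel counts");
  if (c.dense.n_elem != 2) Rcpp::stop("need 2 dense widths");
  int h = c.H, w = c.W;
  for (int l = 0; l < 3; ++l) { h /= 2; w /= 2; }
  if (h < 1 || w < 1)
    Rcpp::stop("input %dx%d too small for three 2x2 pooling stages; "
               "window size must be at least 8 bins", c.H, c.W);
  return c;
}

struct Params {
  std::vector<mat> Wc;     // (Cin*k*k) x Cout, one per conv layer
  std::vector<rowvec> bc;
  std::vector<mat> Wd;     // in x out, three dense (incl. output) layers
  std::vector<rowvec> bd;
};

Params list_to_params(const Rcpp::List& p) {
  Params P;
  Rcpp::List Wc = p["Wc"], bc = p["bc"], Wd = p["Wd"], bd = p["bd"];
  for (int l = 0; l < 4; ++l) {
    P.Wc.push_back(Rcpp::as<mat>(Wc[l]));
    P.bc.push_back(Rcpp::as<rowvec>(bc[l]));
  }
  for (int l = 0; l < 3; ++l) {
    P.Wd.push_back(Rcpp::as<mat>(Wd[l]));
    P.bd.push_back(Rcpp::as<rowvec>(bd[l]));
  }
  return P;
}

Rcpp::List params_to_list(const Params& P) {
  Rcpp::List Wc(4), bc(4), Wd(3), bd(3);
  for (int l = 0; l < 4; ++l) { Wc[l] = P.Wc[l]; bc[l] = P.bc[l]; }
  for (int l = 0; l < 3; ++l) { Wd[l] = P.Wd[l]; bd[l] = P.bd[l]; }
  return Rcpp::List::create(Rcpp::Named("Wc") = Wc, Rcpp::Named("bc") = bc,
                            Rcpp::Named("Wd") = Wd, Rcpp::Named("bd") = bd);
}

// im2col with same-padding: row index r = (dj*k + di)*Cin + c
mat im2col(const cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, pad = k / 2;
  mat cols(C * k * k, H * W, fill::zeros);
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      for (int c = 0; c < C; ++c) {
        const int r = (dj * k + di) * C + c;
        // source pixel (i+di-pad, j+dj-pad) for output (i,j)
        const int oi = di - pad, oj = dj - pad;
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        const mat& sl = x.slice(c);
        for (int j = j0; j < j1; ++j) {
          const double* src = sl.colptr(j + oj) + (i0 + oi);
          double* dst = cols.colptr(0) + r;  // row r, strided access
          for (int i = i0; i < i1; ++i)
            cols(r, (size_t)j * H + i) = src[i - i0];
          (void)dst;
        }
      }
    }
  }
  return cols;
}

// adjoint of im2col: scatter-add columns back into an (H,W,C) cube
cube col2im(const mat& dcols, int H, int W, int C, int k) {
  const int pad = k / 2;
  cube dx(H, W, C, fill::zeros);
  for (int dj = 0; dj < k; ++dj) {
    for (int di = 0; di < k; ++di) {
      for (int c = 0; c < C; ++c) {
        const int r = (dj * k + di) * C + c;
        const int oi = di - pad, oj = dj - pad;
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        mat& sl = dx.slice(c);
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i)
            sl(i + oi, j + oj) += dcols(r, (size_t)j * H + i);
      }
    }
  }
  return dx;
}

// 2x2 stride-2 max pooling, valid truncation; records flat argmax in `idx`
cube maxpool(const cube& a, umat& idx) {
  const int H = a.n_rows, W = a.n_cols, C = a.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube out(Ho, Wo, C);
  idx.set_size((size_t)Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& sl = a.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf; uword bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const uword ii = 2 * i + di, jj = 2 * j + dj;
            const double v = sl(ii, jj);
            if (v > best) { best = v; bi = jj * H + ii; }
          }
        out(i, j, c) = best;
        idx((size_t)j * Ho + i, c) = bi;
      }
    }
  }
  return out;
}

cube unpool(const cube& dout, const umat& idx, int H, int W) {
  const int C = dout.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const vec d = vectorise(dout.slice(c));
    for (uword p = 0; p < d.n_elem; ++p)
      dx.slice(c)(idx(p, c)) += d(p);
  }
  return dx;
}

rowvec softmax(const rowvec& z) {
  rowvec e = exp(z - z.max());
  return e / accu(e);
}

struct Cache {
  std::vector<cube> conv_act;    // tanh activations per conv layer
  std::vector<cube> pool_out;    // pooled maps (layers 0..2)
  std::vector<umat> pool_idx;
  std::vector<mat>  cols;        // im2col inputs per conv layer
  std::vector<int>  h, w;        // spatial dims entering each conv layer
  vec flat;
  std::vector<rowvec> dense_act; // tanh activations of the 2 hidden layers
  rowvec z_out, y_out;
};

rowvec forward_one(const Params& P, const NetCfg& C, const mat& x, Cache* cc) {
  cube a(x.n_rows, x.n_cols, 1);
  a.slice(0) = x;
  Cache local;
  Cache& c = cc ? *cc : local;
  c.conv_act.clear(); c.pool_out.clear(); c.pool_idx.clear();
  c.cols.clear(); c.h.clear(); c.w.clear(); c.dense_act.clear();
  for (int l = 0; l < 4; ++l) {
    c.h.push_back(a.n_rows); c.w.push_back(a.n_cols);
    mat cols = im2col(a, C.k);
    mat z = P.Wc[l].t() * cols;          // Cout x (H*W)
    z.each_col() += P.bc[l].t();
    cube act(a.n_rows, a.n_cols, P.Wc[l].n_cols);
    for (uword ch = 0; ch < act.n_slices; ++ch)
      act.slice(ch) = reshape(tanh(z.row(ch)), a.n_rows, a.n_cols);
    c.cols.push_back(std::move(cols));
    c.conv_act.push_back(act);
    if (l < 3) {
      umat idx;
      a = maxpool(act, idx);
      c.pool_idx.push_back(std::move(idx));
      c.pool_out.push_back(a);
    } else {
      a = act;
    }
  }
  c.flat = vectorise(a);
  rowvec h = c.flat.t();
  for (int l = 0; l < 2; ++l) {
    h = tanh(h * P.Wd[l] + P.bd[l]);
    c.dense_act.push_back(h);
  }
  c.z_out = h * P.Wd[2] + P.bd[2];
  c.y_out = C.softmax_out ? softmax(c.z_out) : c.z_out;
  return c.y_out;
}

// Backward pass from d(loss)/d(output). Accumulates parameter gradients in
// G (same shapes as P); returns gradient w.r.t. the input map if want_dx.
mat backward_one(const Params& P, const NetCfg& C, const Cache& c,
                 rowvec dy, Params* G, bool want_dx) {
  rowvec dz;
  if (C.softmax_out) {
    const rowvec& y = c.y_out;
    dz = y % dy - y * dot(y, dy);
  } else {
    dz = dy;
  }
  // dense stack
  rowvec d = dz;
  for (int l = 2; l >= 0; --l) {
    const rowvec in = (l == 0) ? c.flat.t() : c.dense_act[l - 1];
    if (G) {
      G->Wd[l] += in.t() * d;
      G->bd[l] += d;
    }
    rowvec dprev = d * P.Wd[l].t();
    if (l > 0) dprev %= (1.0 - square(c.dense_act[l - 1]));
    d = dprev;
  }
  // back into conv4 output cube
  int h4 = c.h[3], w4 = c.w[3];
  cube da(h4, w4, P.Wc[3].n_cols);
  {
    vec dv = d.t();
    std::memcpy(da.memptr(), dv.memptr(), sizeof(double) * dv.n_elem);
  }
  for (int l = 3; l >= 0; --l) {
    const cube& act = c.conv_act[l];
    const int H = c.h[l], W = c.w[l];
    const int Cout = act.n_slices;
    // through tanh
    mat dzc(Cout, (size_t)H * W);
    for (int ch = 0; ch < Cout; ++ch) {
      mat g = da.slice(ch) % (1.0 - square(act.slice(ch)));
      dzc.row(ch) = vectorise(g).t();
    }
    if (G) {
      G->Wc[l] += c.cols[l] * dzc.t();
      G->bc[l] += sum(dzc, 1).t();
    }
    if (l == 0 && !want_dx) return mat();
    mat dcols = P.Wc[l] * dzc;
    const int Cin = (l == 0) ? 1 : P.Wc[l - 1].n_cols;
    cube dx = col2im(dcols, H, W, Cin, C.k);
    if (l == 0) return dx.slice(0);
    da = unpool(dx, c.pool_idx[l - 1], c.conv_act[l - 1].n_rows,
                c.conv_act[l - 1].n_cols);
  }
  return mat();
}

Params zeros_like(const Params& P) {
  Params Z;
  for (auto& W : P.Wc) Z.Wc.push_back(mat(W.n_rows, W.n_cols, fill::zeros));
  for (auto& b : P.bc) Z.bc.push_back(rowvec(b.n_elem, fill::zeros));
  for (auto& W : P.Wd) Z.Wd.push_back(mat(W.n_rows, W.n_cols, fill::zeros));
  for (auto& b : P.bd) Z.bd.push_back(rowvec(b.n_elem, fill::zeros));
  return Z;
}

struct Adam {
  Params m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  explicit Adam(const Params& P) : m(zeros_like(P)), v(zeros_like(P)) {}
  template <class T>
  void step_one(T& w, T& mm, T& vv, const T& g, double lr) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    const double bc1 = 1 - std::pow(b1, (double)t);
    const double bc2 = 1 - std::pow(b2, (double)t);
    w -= lr * (mm / bc1) / (sqrt(vv / bc2) + eps);
  }
  void step(Params& P, const Params& G, double lr, bool train_conv) {
    ++t;
    if (train_conv)
      for (int l = 0; l < 4; ++l) {
        step_one(P.Wc[l], m.Wc[l], v.Wc[l], G.Wc[l], lr);
        step_one(P.bc[l], m.bc[l], v.bc[l], G.bc[l], lr);
      }
    for (int l = 0; l < 3; ++l) {
      step_one(P.Wd[l], m.Wd[l], v.Wd[l], G.Wd[l], lr);
      step_one(P.bd[l], m.bd[l], v.bd[l], G.bd[l], lr);
    }
  }
};

double eval_rmse(const Params& P, const NetCfg& C, const cube& X,
                 const mat& Y) {
  double se = 0;
  for (uword i = 0; i < X.n_slices; ++i) {
    rowvec y = forward_one(P, C, X.slice(i), nullptr);
    se += accu(square(y - Y.row(i)));
  }
  return std::sqrt(se / (X.n_slices * C.K));
}

}  // namespace

// [[Rcpp::export(name = ".cnn_init")]]
Rcpp::List cnn_init(Rcpp::List cfg, int seed) {
  NetCfg C = parse_cfg(cfg);
  std::mt19937 rng((unsigned)seed);
  auto glorot = [&](int fan_in, int fan_out, int nr, int nc) {
    const double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> U(-lim, lim);
    mat W(nr, nc);
    for (uword j = 0; j < W.n_cols; ++j)      // column-major fill, fixed order
      for (uword i = 0; i < W.n_rows; ++i) W(i, j) = U(rng);
    return W;
  };
  Params P;
  int cin = 1;
  for (int l = 0; l < 4; ++l) {
    const int cout = C.ch[l];
    P.Wc.push_back(glorot(cin * C.k * C.k, cout, cin * C.k * C.k, cout));
    P.bc.push_back(rowvec(cout, fill::zeros));
    cin = cout;
  }
  int h = C.H, w = C.W;
  for (int l = 0; l < 3; ++l) { h /= 2; w /= 2; }
  int nin = h * w * C.ch[3];
  const int outs[3] = {(int)C.dense[0], (int)C.dense[1], C.K};
  for (int l = 0; l < 3; ++l) {
    P.Wd.push_back(glorot(nin, outs[l], nin, outs[l]));
    P.bd.push_back(rowvec(outs[l], fill::zeros));
    nin = outs[l];
  }
  return params_to_list(P);
}

// [[Rcpp::export(name = ".cnn_predict")]]
arma::mat cnn_predict(Rcpp::List params, Rcpp::List cfg, arma::cube X) {
  NetCfg C = parse_cfg(cfg);
  Params P = list_to_params(params);
  mat out(X.n_slices, C.K);
  for (uword i = 0; i < X.n_slices; ++i)
    out.row(i) = forward_one(P, C, X.slice(i), nullptr);
  return out;
}

// Gradient of output unit `k` (1-based) w.r.t. each input map.
// [[Rcpp::export(name = ".cnn_input_grad")]]
arma::cube cnn_input_grad(Rcpp::List params, Rcpp::List cfg, arma::cube X,
                          int k) {
  NetCfg C = parse_cfg(cfg);
  Params P = list_to_params(params);
  if (k < 1 || k > C.K) Rcpp::stop("output index out of range");
  cube out(X.n_rows, X.n_cols, X.n_slices);
  Cache c;
  for (uword i = 0; i < X.n_slices; ++i) {
    forward_one(P, C, X.slice(i), &c);
    rowvec dy(C.K, fill::zeros);
    dy(k - 1) = 1.0;
    out.slice(i) = backward_one(P, C, c, dy, nullptr, true);
  }
  return out;
}

// MSE loss and its parameter gradient over a batch; used by training and
// exposed for gradient verification.
// [[Rcpp::export(name = ".cnn_loss_grad")]]
Rcpp::List cnn_loss_grad(Rcpp::List params, Rcpp::List cfg, arma::cube X,
                         arma::mat Y) {
  NetCfg C = parse_cfg(cfg);
  Params P = list_to_params(params);
  Params G = zeros_like(P);
  Cache c;
  double loss = 0;
  const uword n = X.n_slices;
  for (uword i = 0; i < n; ++i) {
    rowvec y = forward_one(P, C, X.slice(i), &c);
    rowvec err = y - Y.row(i);
    loss += accu(square(err));
    rowvec dy = 2.0 * err / (double)(n * C.K);
    backward_one(P, C, c, dy, &G, false);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss / (n * C.K),
                            Rcpp::Named("grad") = params_to_list(G));
}

// Minibatch Adam training with MSE loss, RMSE-on-plateau LR decay and
// early stopping on validation RMSE. Returns best-epoch parameters.
// [[Rcpp::export(name = ".cnn_train")]]
Rcpp::List cnn_train(Rcpp::List params, Rcpp::List cfg, arma::cube X,
                     arma::mat Y, arma::cube Xval, arma::mat Yval,
                     Rcpp::List opt) {
  NetCfg C = parse_cfg(cfg);
  Params P = list_to_params(params);
  const double lr0 = Rcpp::as<double>(opt["lr"]);
  const int epochs = Rcpp::as<int>(opt["epochs"]);
  const int batch = Rcpp::as<int>(opt["batch"]);
  const int sched_pat = Rcpp::as<int>(opt["sched_patience"]);
  const double sched_fac = Rcpp::as<double>(opt["sched_factor"]);
  const int es_pat = Rcpp::as<int>(opt["es_patience"]);
  const double es_delta = Rcpp::as<double>(opt["es_min_delta"]);
  const bool train_conv = Rcpp::as<bool>(opt["train_conv"]);
  const int seed = Rcpp::as<int>(opt["seed"]);
  const double min_lr = 1e-6, sched_delta = 1e-4;

  const uword n = X.n_slices;
  std::mt19937 rng((unsigned)seed);
  std::vector<uword> ord(n);
  for (uword i = 0; i < n; ++i) ord[i] = i;

  Adam adam(P);
  double lr = lr0;
  double best = datum::inf, sched_best = datum::inf;
  int es_wait = 0, sched_wait = 0, best_epoch = 0;
  Params best_P = P;
  std::vector<double> h_loss, h_val, h_lr;
  Cache c;

  for (int e = 1; e <= epochs; ++e) {
    std::shuffle(ord.begin(), ord.end(), rng);
    double loss_sum = 0;
    for (uword s = 0; s < n; s += batch) {
      const uword b = std::min((uword)batch, n - s);
      Params G = zeros_like(P);
      for (uword q = 0; q < b; ++q) {
        const uword i = ord[s + q];
        rowvec y = forward_one(P, C, X.slice(i), &c);
        rowvec err = y - Y.row(i);
        loss_sum += accu(square(err));
        rowvec dy = 2.0 * err / (double)(b * C.K);
        backward_one(P, C, c, dy, &G, false);
      }
      adam.step(P, G, lr, train_conv);
      if (!P.Wd[2].is_finite())
        Rcpp::stop("training diverged: non-finite parameters at epoch %d", e);
    }
    const double train_loss = loss_sum / (n * C.K);
    if (!std::isfinite(train_loss))
      Rcpp::stop("training diverged: non-finite loss at epoch %d", e);
    const double val = eval_rmse(P, C, Xval, Yval);
    h_loss.push_back(train_loss); h_val.push_back(val); h_lr.push_back(lr);

    if (val < best - es_delta) {
      best = val; best_P = P; best_epoch = e; es_wait = 0;
    } else if (++es_wait >= es_pat) {
      break;
    }
    if (val < sched_best - sched_delta) {
      sched_best = val; sched_wait = 0;
    } else if (++sched_wait >= sched_pat) {
      lr = std::max(lr * sched_fac, min_lr);
      sched_wait = 0;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = params_to_list(best_P),
      Rcpp::Named("train_loss") = h_loss, Rcpp::Named("val_rmse") = h_val,
      Rcpp::Named("lr") = h_lr, Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val_rmse") = best);
}
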