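// Hot numerical kernels for the 1D-CNN engine: im2col convolution,
// Mish activation, stride-1 same-padded max pooling and the (N,C,L) <->
// (N*L, C) reshape used by batch normalisation. Layout convention matches
// the R side: arrays are column-major (N, C, L).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Forward conv: x (N,C,L), W ((Cin*k) x Cout) with column index c + Cin*j,
// b (Cout). Returns y (N,Cout,Lo) and the im2col matrix for the backward
// pass.
// [[Rcpp::export]]
List conv1d_fw_cpp(NumericVector x, const arma::mat& W,
                   const arma::vec& b, int k, int stride, int pl, int pr) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], Cin = d[1], L = d[2];
  const int Lp = L + pl + pr;
  const int Lo = (Lp - k) / stride + 1;
  const int Cout = W.n_cols;
  if ((int)W.n_rows != Cin * k) stop("conv1d: weight/input channel mismatch");
  arma::mat xc(N * (size_t)Lo, Cin * (size_t)k, arma::fill::zeros);
  const double* xp = x.begin();
  for (int j = 0; j < k; ++j) {
    for (int c = 0; c < Cin; ++c) {
      const size_t col = c + (size_t)Cin * j;
      for (int o = 0; o < Lo; ++o) {
        const int lpad = o * stride + j;      // position in padded axis
        const int l = lpad - pl;
        if (l < 0 || l >= L) continue;
        const double* src = xp + (size_t)N * (c + (size_t)Cin * l);
        double* dst = xc.colptr(col) + (size_t)N * o;
        std::copy(src, src + N, dst);
      }
    }
  }
  arma::mat ym = xc * W;
  ym.each_row() += b.t();
  NumericVector y(N * (size_t)Cout * Lo);
  y.attr("dim") = IntegerVector::create(N, Cout, Lo);
  double* yp = y.begin();
  for (int o = 0; o < Lo; ++o)
    for (int ch = 0; ch < Cout; ++ch) {
      const double* src = ym.colptr(ch) + (size_t)N * o;
      double* dst = yp + (size_t)N * (ch + (size_t)Cout * o);
      std::copy(src, src + N, dst);
    }
  return List::create(_["y"] = y, _["xc"] = xc, _["Lo"] = Lo);
}

// Backward conv. dy (N,Cout,Lo); returns dx (N,Cin,L), dW, db.
// [[Rcpp::export]]
List conv1d_bw_cpp(NumericVector dy, const arma::mat& xc, const arma::mat& W,
                   int N, int Cin, int L, int k, int stride, int pl) {
  IntegerVector d = dy.attr("dim");
  const int Cout = d[1], Lo = d[2];
  arma::mat dym(N * (size_t)Lo, Cout);
  const double* dyp = dy.begin();
  for (int o = 0; o < Lo; ++o)
    for (int ch = 0; ch < Cout; ++ch) {
      const double* src = dyp + (size_t)N * (ch + (size_t)Cout * o);
      double* dst = dym.colptr(ch) + (size_t)N * o;
      std::copy(src, src + N, dst);
    }
  arma::mat dW = xc.t() * dym;
  arma::vec db = arma::sum(dym, 0).t();
  arma::mat dxc = dym * W.t();
  NumericVector dx(N * (size_t)Cin * L);
  dx.attr("dim") = IntegerVector::create(N, Cin, L);
  double* dxp = dx.begin();
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < Cin; ++c) {
      const size_t col = c + (size_t)Cin * j;
      for (int o = 0; o < Lo; ++o) {
        const int l = o * stride + j - pl;
        if (l < 0 || l >= L) continue;
        const double* src = dxc.colptr(col) + (size_t)N * o;
        double* dst = dxp + (size_t)N * (c + (size_t)Cin * l);
        for (int n = 0; n < N; ++n) dst[n] += src[n];
      }
    }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Mish via a single exponential: with u = e^x,
// tanh(softplus(x)) = u(u+2) / (u(u+2) + 2) and sigmoid(x) = u / (1+u).
// Forward returns y, t = tanh(softplus(x)) and s = sigmoid(x), so the
// backward pass is transcendental-free.
// [[Rcpp::export]]
List mish_fw_cpp(NumericVector x) {
  R_xlen_t n = x.size();
  NumericVector y(n), t(n), s(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double u = std::exp(std::min(x[i], 30.0));
    double w = u * (u + 2.0);
    double ti = w / (w + 2.0);
    t[i] = ti;
    s[i] = u / (1.0 + u);
    y[i] = x[i] * ti;
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["t"] = t, _["s"] = s);
}

// [[Rcpp::export]]
NumericVector mish_bw_cpp(NumericVector x, NumericVector t, NumericVector s,
                          NumericVector dy) {
  R_xlen_t n = x.size();
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < n; ++i)
    dx[i] = dy[i] * (t[i] + x[i] * (1.0 - t[i] * t[i]) * s[i]);
  dx.attr("dim") = dy.attr("dim");
  return dx;
}

// stride-1 same-padded max pooling, window k (odd); returns y and argmax
// offsets (1..k).
// [[Rcpp::export]]
List maxpool_same_fw_cpp(NumericVector x, int k) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], L = d[2];
  const int pl = (k - 1) / 2;
  NumericVector y(x.size());
  IntegerVector arg(x.size());
  y.attr("dim") = d; arg.attr("dim") = d;
  const double* xp = x.begin();
  for (int l = 0; l < L; ++l)
    for (int c = 0; c < C; ++c) {
      const size_t out_off = (size_t)N * (c + (size_t)C * l);
      for (int n = 0; n < N; ++n) {
        double best = -std::numeric_limits<double>::infinity();
        int bj = 1;
        for (int j = 0; j < k; ++j) {
          const int ls = l + j - pl;
          if (ls < 0 || ls >= L) continue;
          double v = xp[n + (size_t)N * (c + (size_t)C * ls)];
          if (v > best) { best = v; bj = j + 1; }
        }
        y[out_off + n] = best;
        arg[out_off + n] = bj;
      }
    }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_same_bw_cpp(NumericVector dy, IntegerVector arg, int k) {
  IntegerVector d = dy.attr("dim");
  const int N = d[0], C = d[1], L = d[2];
  const int pl = (k - 1) / 2;
  NumericVector dx(dy.size());
  dx.attr("dim") = d;
  for (int l = 0; l < L; ++l)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)N * (c + (size_t)C * l);
      for (int n = 0; n < N; ++n) {
        const int j = arg[off + n] - 1;
        const int ls = l + j - pl;
        dx[n + (size_t)N * (c + (size_t)C * ls)] += dy[off + n];
      }
    }
  return dx;
}

// aperm(x, c(1,3,2)) specialised: (N,C,L) -> (N,L,C) (and its own inverse
// with C and L swapped). Used to put channels in columns for batch norm.
// [[Rcpp::export]]
NumericVector aperm132_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], L = d[2];
  NumericVector y(x.size());
  y.attr("dim") = IntegerVector::create(N, L, C);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int l = 0; l < L; ++l)
    for (int c = 0; c < C; ++c) {
      const double* src = xp + (size_t)N * (c + (size_t)C * l);
      double* dst = yp + (size_t)N * (l + (size_t)L * c);
      std::copy(src, src + N, dst);
    }
  return y;
}

// Batch normalisation on (N,C,L) arrays (per channel over N*L) or (N,D)
// matrices passed as (N,D,1). Training mode computes batch statistics.
// [[Rcpp::export]]
List bn_fw_cpp(NumericVector x, const arma::vec& gamma, const arma::vec& beta,
               arma::vec mu, arma::vec var, bool train, double eps) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], L = d[2];
  const size_t m = (size_t)N * L;
  if (train) {
    mu.zeros(C); var.zeros(C);
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int l = 0; l < L; ++l) {
        const double* xp = x.begin() + (size_t)N * (c + (size_t)C * l);
        for (int n = 0; n < N; ++n) { s += xp[n]; s2 += xp[n] * xp[n]; }
      }
      mu[c] = s / m;
      var[c] = std::max(s2 / m - mu[c] * mu[c], 0.0);
    }
  }
  arma::vec istd = 1.0 / arma::sqrt(var + eps);
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    const double a = gamma[c] * istd[c];
    const double b = beta[c] - a * mu[c];
    for (int l = 0; l < L; ++l) {
      const size_t off = (size_t)N * (c + (size_t)C * l);
      for (int n = 0; n < N; ++n) y[off + n] = a * x[off + n] + b;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["var"] = var,
                      _["istd"] = istd);
}

// [[Rcpp::export]]
List bn_bw_cpp(NumericVector dy, NumericVector x, const arma::vec& mu,
               const arma::vec& istd, const arma::vec& gamma, bool train) {
  IntegerVector d = dy.attr("dim");
  const int N = d[0], C = d[1], L = d[2];
  const size_t m = (size_t)N * L;
  NumericVector dx(dy.size());
  dx.attr("dim") = d;
  arma::vec dgamma(C, arma::fill::zeros), dbeta(C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int l = 0; l < L; ++l) {
      const size_t off = (size_t)N * (c + (size_t)C * l);
      for (int n = 0; n < N; ++n) {
        const double xh = (x[off + n] - mu[c]) * istd[c];
        dgamma[c] += dy[off + n] * xh;
        dbeta[c] += dy[off + n];
        s1 += dy[off + n];
        s2 += dy[off + n] * xh;
      }
    }
    if (train) {
      const double a = gamma[c] * istd[c];
      const double m1 = s1 / m, m2 = s2 / m;
      for (int l = 0; l < L; ++l) {
        const size_t off = (size_t)N * (c + (size_t)C * l);
        for (int n = 0; n < N; ++n) {
          const double xh = (x[off + n] - mu[c]) * istd[c];
          dx[off + n] = a * (dy[off + n] - m1 - xh * m2);
        }
      }
    } else {
      const double a = gamma[c] * istd[c];
      for (int l = 0; l < L; ++l) {
        const size_t off = (size_t)N * (c + (size_t)C * l);
        for (int n = 0; n < N; ++n) dx[off + n] = a * dy[off + n];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// CBAM pooling helpers. Channel pools: over positions L for each (n,c);
// spatial pools: over channels C for each (n,l).
// [[Rcpp::export]]
List cbam_chan_pool_fw_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], L = d[2];
  NumericMatrix avg(N, C), mx(N, C);
  IntegerMatrix arg(N, C);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      double s = 0, best = -std::numeric_limits<double>::infinity();
      int bl = 1;
      for (int l = 0; l < L; ++l) {
        const double v = x[n + (size_t)N * (c + (size_t)C * l)];
        s += v;
        if (v > best) { best = v; bl = l + 1; }
      }
      avg(n, c) = s / L; mx(n, c) = best; arg(n, c) = bl;
    }
  return List::create(_["avg"] = avg, _["max"] = mx, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cbam_chan_pool_bw_cpp(NumericMatrix davg, NumericMatrix dmax,
                                    IntegerMatrix arg, int L) {
  const int N = davg.nrow(), C = davg.ncol();
  NumericVector dx((size_t)N * C * L);
  dx.attr("dim") = IntegerVector::create(N, C, L);
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double a = davg(n, c) / L;
      for (int l = 0; l < L; ++l)
        dx[n + (size_t)N * (c + (size_t)C * l)] = a;
      dx[n + (size_t)N * (c + (size_t)C * (arg(n, c) - 1))] += dmax(n, c);
    }
  return dx;
}

// [[Rcpp::export]]
List cbam_spat_pool_fw_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], L = d[2];
  NumericMatrix avg(N, L), mx(N, L);
  IntegerMatrix arg(N, L);
  for (int l = 0; l < L; ++l)
    for (int n = 0; n < N; ++n) {
      double s = 0, best = -std::numeric_limits<double>::infinity();
      int bc = 1;
      for (int c = 0; c < C; ++c) {
        const double v = x[n + (size_t)N * (c + (size_t)C * l)];
        s += v;
        if (v > best) { best = v; bc = c + 1; }
      }
      avg(n, l) = s / C; mx(n, l) = best; arg(n, l) = bc;
    }
  return List::create(_["avg"] = avg, _["max"] = mx, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cbam_spat_pool_bw_cpp(NumericMatrix davg, NumericMatrix dmax,
                                    IntegerMatrix arg, int C) {
  const int N = davg.nrow(), L = davg.ncol();
  NumericVector dx((size_t)N * C * L);
  dx.attr("dim") = IntegerVector::create(N, C, L);
  for (int l = 0; l < L; ++l)
    for (int n = 0; n < N; ++n) {
      const double a = davg(n, l) / C;
      for (int c = 0; c < C; ++c)
        dx[n + (size_t)N * (c + (size_t)C * l)] = a;
      dx[n + (size_t)N * ((arg(n, l) - 1) + (size_t)C * l)] += dmax(n, l);
    }
  return dx;
}

// y = x * mc (broadcast over L) where mc is (N,C)
// [[Rcpp::export]]
NumericVector bcast_mul_nc_cpp(NumericVector x, NumericMatrix mc) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], L = d[2];
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int l = 0; l < L; ++l)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)N * (c + (size_t)C * l);
      for (int n = 0; n < N; ++n) y[off + n] = x[off + n] * mc(n, c);
    }
  return y;
}

// y = x * ms (broadcast over C) where ms is (N,L)
// [[Rcpp::export]]
NumericVector bcast_mul_nl_cpp(NumericVector x, NumericMatrix ms) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], C = d[1], L = d[2];
  NumericVector y(x.size());
  y.attr("dim") = d;
  for (int l = 0; l < L; ++l)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)N * (c + (size_t)C * l);
      for (int n = 0; n < N; ++n) y[off + n] = x[off + n] * ms(n, l);
    }
  return y;
}

// rowSums over channels of elementwise product: out(n,l) = sum_c a*b
// [[Rcpp::export]]
NumericMatrix sum_prod_nl_cpp(NumericVector a, NumericVector b) {
  IntegerVector d = a.attr("dim");
  const int N = d[0], C = d[1], L = d[2];
  NumericMatrix out(N, L);
  for (int l = 0; l < L; ++l)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)N * (c + (size_t)C * l);
      for (int n = 0; n < N; ++n) out(n, l) += a[off + n] * b[off + n];
    }
  return out;
}

// rowSums over positions of elementwise product: out(n,c) = sum_l a*b
// [[Rcpp::export]]
NumericMatrix sum_prod_nc_cpp(NumericVector a, NumericVector b) {
  IntegerVector d = a.attr("dim");
  const int N = d[0], C = d[1], L = d[2];
  NumericMatrix out(N, C);
  for (int l = 0; l < L; ++l)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)N * (c + (size_t)C * l);
      for (int n = 0; n < N; ++n) out(n, c) += a[off + n] * b[off + n];
    }
  return out;
}

// One AdamW update, in place. `par`, `g`, `m`, `v` share length; `lam` adds
// the loss-side L2 gradient 2*lam*par (weights only), `wd` is decoupled
// decay. All four vectors are owned by the layer environment; snapshots are
// taken as copies, so in-place mutation is safe.
// [[Rcpp::export]]
void adamw_update_cpp(NumericVector par, NumericVector g, NumericVector m,
                      NumericVector v, double lr, double lam, double wd,
                      double beta1, double beta2, double eps,
                      double b1t, double b2t) {
  R_xlen_t n = par.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i] + 2.0 * lam * par[i];
    double mi = beta1 * m[i] + (1.0 - beta1) * gi;
    double vi = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    m[i] = mi; v[i] = vi;
    double upd = (mi / b1t) / (std::sqrt(vi / b2t) + eps) + wd * par[i];
    par[i] -= lr * upd;
  }
}

// Dual coordinate descent for epsilon-SVR with the bias absorbed into the
// kernel (Ka = K + 1). beta_i in [-C, C]; soft-threshold closed-form update
// per coordinate; deterministic sweep order.
// [[Rcpp::export]]
arma::vec svr_cd_cpp(const arma::mat& Ka, const arma::vec& y, double C,
                     double eps, double tol, int max_pass) {
  const int n = y.n_elem;
  arma::vec beta(n, arma::fill::zeros), f(n, arma::fill::zeros);
  arma::vec diagKa = Ka.diag();
  for (int pass = 0; pass < max_pass; ++pass) {
    double delta_max = 0;
    for (int i = 0; i < n; ++i) {
      const double r = y[i] - (f[i] - diagKa[i] * beta[i]);
      double b = 0;
      const double a = std::fabs(r) - eps;
      if (a > 0) b = (r > 0 ? a : -a) / diagKa[i];
      b = std::max(-C, std::min(C, b));
      const double db = b - beta[i];
      if (db != 0) {
        f += db * Ka.col(i);
        beta[i] = b;
        delta_max = std::max(delta_max, std::fabs(db));
      }
    }
    if (delta_max < tol * std::max(C, 1.0)) break;
  }
  return beta;
}
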