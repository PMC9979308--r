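// Core numerical kernels: greedy sparse coding (OMP), K-SVD-style
// dictionary learning, and the small convolutional reconstruction network.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <functional>
#include <random>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Orthogonal matching pursuit
// ---------------------------------------------------------------------------

// Greedy selection with orthogonal re-projection after every pick.
// D: p x K with unit-norm atoms. Returns dense coefficient vector (K).
static arma::vec omp_single(const arma::mat& D, const arma::vec& y, int T,
                            double res_tol) {
  const int K = D.n_cols;
  arma::vec x(K, arma::fill::zeros);
  if (T <= 0) return x;
  if (T > K) T = K;
  arma::vec r = y;
  std::vector<unsigned int> support;
  support.reserve(T);
  std::vector<bool> used(K, false);
  for (int t = 0; t < T; ++t) {
    if (arma::norm(r) <= res_tol) break;
    arma::vec c = D.t() * r;
    int best = -1;
    double bestv = -1.0;
    for (int k = 0; k < K; ++k) {
      if (used[k]) continue;
      double v = std::fabs(c(k));
      if (v > bestv) { bestv = v; best = k; }
    }
    if (best < 0 || bestv <= 1e-14) break;
    used[best] = true;
    support.push_back(best);
    arma::uvec S(support.size());
    for (size_t i = 0; i < support.size(); ++i) S(i) = support[i];
    arma::mat Ds = D.cols(S);
    arma::vec coef;
    if (!arma::solve(coef, Ds.t() * Ds, Ds.t() * y, arma::solve_opts::likely_sympd))
      coef = arma::pinv(Ds) * y;
    r = y - Ds * coef;
    x.zeros();
    for (size_t i = 0; i < support.size(); ++i) x(support[i]) = coef(i);
  }
  return x;
}

// [[Rcpp::export(name = ".omp_batch_cpp")]]
arma::mat omp_batch_cpp(const arma::mat& D, const arma::mat& Y, int T,
                        double res_tol = 1e-12) {
  arma::mat X(D.n_cols, Y.n_cols, arma::fill::zeros);
  for (arma::uword i = 0; i < Y.n_cols; ++i)
    X.col(i) = omp_single(D, Y.col(i), T, res_tol);
  return X;
}

// ---------------------------------------------------------------------------
// K-SVD-style dictionary learning
// ---------------------------------------------------------------------------

// 1-opt support refinement: try swapping each selected atom for the best
// alternative under a least-squares refit; keeps ||x||_0 <= T and never
// worsens the column residual
static arma::vec refine_support(const arma::mat& D, const arma::vec& y,
                                arma::vec x) {
  const int K = D.n_cols;
  for (int pass = 0; pass < 3; ++pass) {
    arma::uvec S = arma::find(arma::abs(x) > 0);
    if (S.n_elem == 0) break;
    bool improved = false;
    for (arma::uword si = 0; si < S.n_elem; ++si) {
      arma::uvec S2 = S;
      S2.shed_row(si);
      arma::vec r2;
      arma::vec coef2;
      if (S2.n_elem == 0) {
        r2 = y;
      } else {
        arma::mat Ds = D.cols(S2);
        if (!arma::solve(coef2, Ds.t() * Ds, Ds.t() * y,
                         arma::solve_opts::likely_sympd))
          coef2 = arma::pinv(Ds) * y;
        r2 = y - Ds * coef2;
      }
      arma::vec c = D.t() * r2;
      for (arma::uword j = 0; j < S2.n_elem; ++j) c(S2(j)) = 0;
      arma::uword jbest = arma::index_max(arma::abs(c));
      if (jbest == S(si)) continue;
      arma::uvec Snew(S2.n_elem + 1);
      for (arma::uword j = 0; j < S2.n_elem; ++j) Snew(j) = S2(j);
      Snew(S2.n_elem) = jbest;
      arma::mat Dn = D.cols(Snew);
      arma::vec coefn;
      if (!arma::solve(coefn, Dn.t() * Dn, Dn.t() * y,
                       arma::solve_opts::likely_sympd))
        coefn = arma::pinv(Dn) * y;
      double res_old = arma::norm(y - D * x);
      double res_new = arma::norm(y - Dn * coefn);
      if (res_new < res_old - 1e-12) {
        x.zeros();
        for (arma::uword j = 0; j < Snew.n_elem; ++j) x(Snew(j)) = coefn(j);
        S = arma::find(arma::abs(x) > 0);
        improved = true;
        break; // restart the scan on the new support
      }
    }
    if (!improved) break;
  }
  return x;
}

// exact T-sparse coding by support enumeration; only used for tiny
// dictionaries where it is cheap (the l0 subproblem solved to optimality)
static arma::vec exhaustive_code(const arma::mat& D, const arma::vec& y,
                                 int T) {
  const int K = D.n_cols;
  std::vector<int> idx(T);
  arma::vec best(K, arma::fill::zeros);
  double best_res = arma::norm(y);
  std::function<void(int, int)> rec = [&](int start, int depth) {
    if (depth == T) {
      arma::uvec S(T);
      for (int t = 0; t < T; ++t) S(t) = idx[t];
      arma::mat Ds = D.cols(S);
      arma::vec coef;
      if (!arma::solve(coef, Ds.t() * Ds, Ds.t() * y,
                       arma::solve_opts::likely_sympd))
        return;
      double res = arma::norm(y - Ds * coef);
      if (res < best_res) {
        best_res = res;
        best.zeros();
        for (int t = 0; t < T; ++t) best(idx[t]) = coef(t);
      }
      return;
    }
    for (int k = start; k <= K - (T - depth); ++k) {
      idx[depth] = k;
      rec(k + 1, depth + 1);
    }
  };
  rec(0, 0);
  return best;
}

// one coding pass with per-column monotone guard, then sequential rank-1
// atom refits on each atom's support; returns the resulting objective
static double ksvd_sweep(const arma::mat& Y, arma::mat& D, arma::mat& X,
                         int T, double res_tol, bool recode) {
  const arma::uword K = D.n_cols;
  if (recode) {
    arma::mat Xn = omp_batch_cpp(D, Y, T, res_tol);
    for (arma::uword i = 0; i < Y.n_cols; ++i) {
      arma::vec xi = refine_support(D, Y.col(i), Xn.col(i));
      double old_r = arma::norm(Y.col(i) - D * X.col(i));
      double new_r = arma::norm(Y.col(i) - D * xi);
      if (new_r <= old_r) X.col(i) = xi;
    }
  }
  arma::mat R = Y - D * X;
  for (arma::uword k = 0; k < K; ++k) {
    arma::uvec omega = arma::find(arma::abs(X.row(k).t()) > 0);
    if (omega.n_elem == 0) continue;
    // restricted residual including atom k's current contribution
    arma::mat Ek = R.cols(omega) + D.col(k) * X.submat(arma::uvec{k}, omega);
    arma::mat U, V;
    arma::vec s;
    if (arma::svd_econ(U, s, V, Ek, "both") && s.n_elem > 0 && s(0) > 0) {
      D.col(k) = U.col(0);
      arma::rowvec xk = s(0) * V.col(0).t();
      X.submat(arma::uvec{k}, omega) = xk;
      R.cols(omega) = Ek - D.col(k) * xk;
    }
  }
  return arma::accu(arma::square(Y - D * X));
}

// re-seed unused atoms (zero coefficients, so the objective is unchanged)
// and near-duplicate atoms (coherence > 0.99 with an earlier atom) from the
// worst-represented columns
static bool reseed_atoms(const arma::mat& Y, arma::mat& D, arma::mat& X,
                         bool aggressive, int episode) {
  const arma::uword K = D.n_cols;
  arma::rowvec colres = arma::sum(arma::square(Y - D * X), 0);
  // episode-keyed PRNG so successive stall episodes explore different
  // sacrifices and seeding columns (deterministic for a given call)
  std::mt19937 rng(2654435761u * (unsigned)(episode + 1) + (unsigned)K);
  arma::mat G = arma::abs(D.t() * D);
  arma::vec rowE(K);
  for (arma::uword k = 0; k < K; ++k)
    rowE(k) = arma::accu(arma::square(X.row(k)));
  // when stalled, sacrifice the atom whose columns are worst represented
  // ("badness"), cycling through candidates across stall episodes
  std::vector<bool> sacrificed(K, false);
  if (aggressive) {
    arma::vec badness(K, arma::fill::zeros);
    for (arma::uword k = 0; k < K; ++k) {
      arma::uvec omega = arma::find(arma::abs(X.row(k).t()) > 0);
      if (omega.n_elem == 0) continue;
      badness(k) = arma::mean(colres.elem(omega));
    }
    arma::uvec ord = arma::sort_index(badness, "descend");
    // sacrifice one or two atoms drawn from the worst-serving candidates
    int ncand = std::min<int>(8, K);
    int n_sac = 1 + (episode % 2);
    for (int t = 0; t < n_sac; ++t)
      sacrificed[ord(rng() % ncand)] = true;
  }
  bool changed = false;
  for (arma::uword k = 0; k < K; ++k) {
    bool unused = rowE(k) == 0;
    bool duplicate = (k > 0) && (arma::max(G(k, arma::span(0, k - 1))) > 0.99);
    bool rare = aggressive && sacrificed[k];
    if (!unused && !duplicate && !rare) continue;
    arma::uword worst = colres.index_max();
    if (aggressive) {
      // draw the seeding column from the worst-coded quantile
      arma::uvec colord = arma::sort_index(colres.t(), "descend");
      int pool = std::min<int>(16, colord.n_elem);
      for (int tries = 0; tries < 8; ++tries) {
        arma::uword cand = colord(rng() % pool);
        if (colres(cand) > 0) { worst = cand; break; }
      }
    }
    // seed from the unexplained direction of the worst-coded column
    // (excluding atom k's own contribution, which is being discarded)
    arma::vec r = Y.col(worst) - D * X.col(worst) + D.col(k) * X(k, worst);
    double nrm = arma::norm(r);
    if (nrm <= 1e-8) { // fully explained: fall back to the raw column
      r = Y.col(worst);
      nrm = arma::norm(r);
      if (nrm <= 1e-12) continue;
    }
    D.col(k) = r / nrm;
    X.row(k).zeros();
    colres(worst) = 0; // do not reuse the same column twice
    changed = true;
  }
  return changed;
}

// Alternates batch OMP with sequential rank-1 atom refits (K-SVD style).
// The recorded objective trace is non-increasing by construction: new codes
// are only accepted per column when they do not worsen that column's
// residual, the rank-1 refit is the exact minimizer of its restricted
// subproblem, and the re-seeding of unused/near-duplicate atoms is guarded:
// if a sweep from the re-seeded dictionary would end above the previous
// objective, the iteration falls back to a sweep without re-seeding.
// [[Rcpp::export(name = ".ksvd_cpp")]]
List ksvd_cpp(const arma::mat& Y, const arma::mat& D0, int T, int iters,
              double res_tol = 1e-12) {
  const arma::uword K = D0.n_cols;
  arma::mat D = D0;
  arma::mat X = omp_batch_cpp(D, Y, T, res_tol);
  double obj = arma::accu(arma::square(Y - D * X));
  std::vector<double> trace;
  trace.push_back(obj);

  double prev_accepted = obj;
  bool stalled = false;
  int episode = 0, stall_depth = 0, restarts = 0;
  for (int it = 0; it < iters; ++it) {
    arma::mat Dr = D, Xr = X;
    if (stalled) { ++episode; ++stall_depth; } else stall_depth = 0;
    bool reseeded = (it > 0) && reseed_atoms(Y, Dr, Xr, stalled, episode);
    double obj_new = ksvd_sweep(Y, Dr, Xr, T, res_tol, it > 0);
    if (reseeded && obj_new > obj) {
      // let re-seeded atoms settle: a few extra internal sweeps before
      // deciding (an outer iteration may comprise several sweeps)
      for (int j = 0; j < 11 && obj_new > obj; ++j)
        obj_new = ksvd_sweep(Y, Dr, Xr, T, res_tol, true);
    }
    if (reseeded && obj_new > obj) {
      // fall back: a plain sweep without re-seeding keeps the guarantee
      Dr = D; Xr = X;
      obj_new = ksvd_sweep(Y, Dr, Xr, T, res_tol, it > 0);
    }
    if (obj_new <= obj) { D = Dr; X = Xr; obj = obj_new; }
    // deep stall: try a fresh start from other data columns, accepted
    // only if it ends below the incumbent (the trace stays monotone)
    if (stall_depth > 0 && stall_depth % 40 == 0 && restarts < 6) {
      ++restarts;
      std::mt19937 rr(88172645u * (unsigned)restarts + (unsigned)Y.n_cols);
      arma::mat D2(D.n_rows, K);
      for (arma::uword k = 0; k < K; ++k) {
        arma::vec cand = Y.col(rr() % Y.n_cols);
        double nn = arma::norm(cand);
        D2.col(k) = nn > 1e-12 ? arma::vec(cand / nn)
                               : arma::vec(D.col(k));
      }
      arma::mat X2 = omp_batch_cpp(D2, Y, T, res_tol);
      double obj2 = arma::accu(arma::square(Y - D2 * X2));
      for (int j = 0; j < 120 && obj2 > obj; ++j) {
        reseed_atoms(Y, D2, X2, j % 10 == 9, j + 1000 * restarts);
        obj2 = ksvd_sweep(Y, D2, X2, T, res_tol, true);
      }
      if (obj2 <= obj) { D = D2; X = X2; obj = obj2; stall_depth = 0; }
    }
    // exact enumeration for a few stubborn columns once the dictionary
    // fits the bulk of the data; cheap only for tiny (K, T)
    if (T <= 3 && (int)D.n_cols <= 64) {
      arma::vec res(Y.n_cols), rel(Y.n_cols);
      for (arma::uword i = 0; i < Y.n_cols; ++i) {
        res(i) = arma::norm(Y.col(i) - D * X.col(i));
        rel(i) = res(i) / std::max(arma::norm(Y.col(i)), 1e-12);
      }
      if (arma::median(rel) < 5e-2) {
        arma::uvec ord = arma::sort_index(rel, "descend");
        int budget = std::min<int>(10, Y.n_cols);
        for (int t = 0; t < budget; ++t) {
          arma::uword i = ord(t);
          if (rel(i) < 1e-3) break;
          arma::vec xe = exhaustive_code(D, Y.col(i), T);
          if (arma::norm(Y.col(i) - D * xe) < res(i)) X.col(i) = xe;
        }
        obj = arma::accu(arma::square(Y - D * X));
      }
    }
    stalled = (prev_accepted - obj) <= 1e-4 * std::max(1e-12, prev_accepted);
    prev_accepted = obj;
    trace.push_back(obj);
    if (obj <= 1e-12 * arma::accu(arma::square(Y))) {
      for (int j = it + 1; j < iters; ++j) trace.push_back(obj);
      break; // converged: pad the trace to its full length
    }
  }
  return List::create(_["D"] = D, _["X"] = X,
                      _["objective"] = NumericVector(trace.begin(), trace.end()));
}

// ---------------------------------------------------------------------------
// Convolutional network (same-padding conv stack, ReLU between layers)
// ---------------------------------------------------------------------------

// im2col with zero padding for odd square-ish kernels.
// X: (H, W, Cin) cube -> (kh*kw*Cin) x (H*W)
static arma::mat im2col(const arma::cube& X, int kh, int kw) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::mat out(kh * kw * C, H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        const int row = c * kh * kw + dj * kh + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pw;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - ph;
            if (si < 0 || si >= H) continue;
            out(row, j * H + i) = X(si, sj, c);
          }
        }
      }
  return out;
}

// adjoint of im2col: scatter-add columns back into an (H, W, C) cube
static arma::cube col2im(const arma::mat& cols, int H, int W, int C, int kh,
                         int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::cube X(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dj = 0; dj < kw; ++dj)
      for (int di = 0; di < kh; ++di) {
        const int row = c * kh * kw + dj * kh + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pw;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - ph;
            if (si < 0 || si >= H) continue;
            X(si, sj, c) += cols(row, j * H + i);
          }
        }
      }
  return X;
}

struct LayerSpec {
  int kh, kw, cin, cout;
  arma::mat Wm; // (kh*kw*cin) x cout
  arma::vec b;  // cout
};

static std::vector<LayerSpec> parse_layers(const List& layers) {
  std::vector<LayerSpec> out;
  for (int l = 0; l < layers.size(); ++l) {
    List lay = layers[l];
    NumericVector w = lay["w"];
    IntegerVector dm = w.attr("dim");
    if (dm.size() != 4) stop("layer weight must be a 4-D array (kh,kw,cin,cout)");
    LayerSpec s;
    s.kh = dm[0]; s.kw = dm[1]; s.cin = dm[2]; s.cout = dm[3];
    if (s.kh % 2 == 0 || s.kw % 2 == 0) stop("kernel sides must be odd");
    s.Wm = arma::mat(w.begin(), s.kh * s.kw * s.cin, s.cout);
    NumericVector bb = lay["b"];
    if ((int)bb.size() != s.cout) stop("bias length must equal output channels");
    s.b = arma::vec(bb.begin(), s.cout);
    out.push_back(s);
  }
  for (size_t l = 1; l < out.size(); ++l)
    if (out[l].cin != out[l - 1].cout) stop("channel mismatch between layers");
  return out;
}

// forward pass; optionally keep caches for backprop
static arma::cube net_forward(const std::vector<LayerSpec>& net,
                              const arma::mat& x,
                              std::vector<arma::mat>* cols_cache,
                              std::vector<arma::cube>* act_cache) {
  const int H = x.n_rows, W = x.n_cols;
  arma::cube cur(H, W, 1);
  cur.slice(0) = x;
  const int L = net.size();
  for (int l = 0; l < L; ++l) {
    const LayerSpec& s = net[l];
    if ((int)cur.n_slices != s.cin) stop("channel mismatch with input");
    arma::mat cols = im2col(cur, s.kh, s.kw);
    if (cols_cache) cols_cache->push_back(cols);
    arma::mat o = s.Wm.t() * cols; // cout x (H*W)
    o.each_col() += s.b;
    arma::cube nxt(H, W, s.cout);
    for (int c = 0; c < s.cout; ++c)
      nxt.slice(c) = arma::reshape(o.row(c).t(), H, W);
    if (l < L - 1) nxt.transform([](double v) { return v > 0 ? v : 0.0; });
    if (act_cache) act_cache->push_back(nxt);
    cur = nxt;
  }
  return cur;
}

// [[Rcpp::export(name = ".deep_forward_cpp")]]
arma::mat deep_forward_cpp(const arma::mat& x, const List& layers) {
  std::vector<LayerSpec> net = parse_layers(layers);
  arma::cube out = net_forward(net, x, nullptr, nullptr);
  if (out.n_slices != 1) stop("network must end in a single output channel");
  return out.slice(0);
}

// Sum of squared-error data costs and parameter gradients over a batch:
//   data cost  = (1/n) * sum_i 0.5 * ||h(x_i) - y_i||^2   (sum over pixels)
// Gradients are of the data cost only; weight decay is added by the caller.
// [[Rcpp::export(name = ".deep_batch_grad_cpp")]]
List deep_batch_grad_cpp(const List& xs, const List& ys, const List& layers) {
  std::vector<LayerSpec> net = parse_layers(layers);
  const int n = xs.size();
  if (n == 0 || ys.size() != n) stop("empty or mismatched batch");
  const int L = net.size();
  std::vector<arma::mat> gW(L);
  std::vector<arma::vec> gb(L);
  for (int l = 0; l < L; ++l) {
    gW[l].zeros(net[l].Wm.n_rows, net[l].Wm.n_cols);
    gb[l].zeros(net[l].cout);
  }
  double cost = 0.0;
  for (int i = 0; i < n; ++i) {
    arma::mat x = as<arma::mat>(xs[i]);
    arma::mat y = as<arma::mat>(ys[i]);
    const int H = x.n_rows, W = x.n_cols;
    std::vector<arma::mat> cols;
    std::vector<arma::cube> acts;
    arma::cube out = net_forward(net, x, &cols, &acts);
    arma::mat diff = out.slice(0) - y;
    cost += 0.5 * arma::accu(arma::square(diff));
    // backprop
    arma::cube delta(H, W, 1);
    delta.slice(0) = diff;
    for (int l = L - 1; l >= 0; --l) {
      const LayerSpec& s = net[l];
      arma::mat dOut(s.cout, H * W);
      for (int c = 0; c < s.cout; ++c)
        dOut.row(c) = arma::vectorise(delta.slice(c)).t();
      gW[l] += cols[l] * dOut.t();
      gb[l] += arma::sum(dOut, 1);
      if (l > 0) {
        arma::mat dCols = s.Wm * dOut; // (kh*kw*cin) x (H*W)
        arma::cube dIn = col2im(dCols, H, W, s.cin, s.kh, s.kw);
        const arma::cube& a = acts[l - 1]; // post-ReLU activation
        for (int c = 0; c < s.cin; ++c)
          dIn.slice(c) %= arma::conv_to<arma::mat>::from(a.slice(c) > 0);
        delta = dIn;
      }
    }
  }
  cost /= n;
  List gws(L), gbs(L);
  for (int l = 0; l < L; ++l) {
    NumericVector w(gW[l].begin(), gW[l].end());
    w.attr("dim") = IntegerVector::create(net[l].kh, net[l].kw, net[l].cin,
                                          net[l].cout);
    gws[l] = NumericVector(w) ;
    gbs[l] = NumericVector(gb[l].begin(), gb[l].end());
  }
  for (int l = 0; l < L; ++l) {
    NumericVector w = gws[l];
    for (double& v : w) v /= n;
    NumericVector bvec = gbs[l];
    for (double& v : bvec) v /= n;
  }
  return List::create(_["data_cost"] = cost, _["grad_w"] = gws,
                      _["grad_b"] = gbs);
}
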