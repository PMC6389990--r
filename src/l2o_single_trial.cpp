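// Exhaustive leave-two-out evaluation on single-trial data, in gram form.
//
// The gram matrix G = B B' of the (uncentered) trial-by-voxel betas is
// precomputed once in R. For every unordered target pair the trials of both
// targets are removed from the training set; the gram submatrix is double-
// centered (equivalent to column-centering the predictors with training-fold
// means), the ridge system is factorized once, and predictions for all held-
// out trials are obtained for every coordinate model from the same
// factorization. Same-target folds (train without one target, predict its
// trials) are evaluated separately and reported as their own stratum.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static double cos_dist(const arma::rowvec& a, const arma::rowvec& b) {
  double na = arma::norm(a, 2), nb = arma::norm(b, 2);
  if (na == 0.0 || nb == 0.0)
    stop("Cosine distance is undefined for a zero-norm vector.");
  return 1.0 - arma::dot(a, b) / (na * nb);
}

static double gcv_pick(const arma::vec& w, const arma::vec& T, double total,
                       int n, const arma::vec& grid) {
  double best = arma::datum::inf, best_l = grid(0);
  for (arma::uword g = 0; g < grid.n_elem; ++g) {
    double lambda = grid(g), rss = total, df = 1.0;
    for (arma::uword i = 0; i < w.n_elem; ++i) {
      double f = w(i) / (w(i) + lambda);
      rss -= (2.0 * f - f * f) * T(i);
      df += f;
    }
    if (rss < 0) rss = 0;
    if (n - df <= 0) continue;
    double score = n * rss / ((n - df) * (n - df));
    if (score < best) { best = score; best_l = lambda; }
  }
  return best_l;
}

// Evaluate one fold for all models; appends pair rows to the per-model output.
static void eval_fold(const arma::mat& G,
                      const std::vector<arma::mat>& Y,
                      const std::vector<arma::mat>& Ytruth,
                      const arma::uvec& train, const arma::uvec& test_i,
                      const arma::uvec& test_j, bool same_target,
                      double lambda, bool use_gcv,
                      std::vector<std::vector<double>>& rows,
                      std::vector<double>& fold_lambdas) {
  const int n = train.n_elem;
  const arma::uvec test = arma::join_cols(test_i, test_j);
  arma::mat Gtt = G.submat(train, train);
  arma::rowvec rm = arma::mean(Gtt, 0);
  double mm = arma::mean(rm);
  arma::mat Kc = Gtt;
  Kc.each_row() -= rm;
  Kc.each_col() -= rm.t();
  Kc += mm;
  arma::mat Gxt = G.submat(test, train);
  arma::vec tm = arma::mean(Gxt, 1);
  arma::mat kc = Gxt;
  kc.each_col() -= tm;
  kc.each_row() -= rm;
  kc += mm;

  const size_t n_models = Y.size();
  std::vector<arma::mat> preds(n_models);

  if (use_gcv) {
    arma::vec w; arma::mat Q;
    arma::eig_sym(w, Q, Kc);
    w.transform([](double v) { return v > 0 ? v : 0.0; });
    arma::vec wpos = w(arma::find(w > w.max() * 1e-12));
    double scale = wpos.n_elem ? arma::mean(wpos) : 1.0;
    arma::vec grid(41);
    for (int g = 0; g < 41; ++g) grid(g) = scale * std::pow(10.0, -5.0 + 10.0 * g / 40.0);
    arma::mat kcQ = kc * Q;
    for (size_t m = 0; m < n_models; ++m) {
      arma::mat Ytr = Y[m].rows(train);
      arma::rowvec ybar = arma::mean(Ytr, 0);
      Ytr.each_row() -= ybar;
      arma::mat B = Q.t() * Ytr;
      arma::vec T = arma::sum(arma::square(B), 1);
      double lam = gcv_pick(w, T, arma::accu(arma::square(Ytr)), n, grid);
      fold_lambdas.push_back(lam);
      arma::vec inv = 1.0 / (w + lam);
      arma::mat P = kcQ * (B.each_col() % inv);
      P.each_row() += ybar;
      preds[m] = P;
    }
  } else {
    arma::mat A = Kc;
    A.diag() += lambda;
    arma::mat H = arma::solve(A, kc.t(), arma::solve_opts::likely_sympd).t();
    for (size_t m = 0; m < n_models; ++m) {
      arma::mat Ytr = Y[m].rows(train);
      arma::rowvec ybar = arma::mean(Ytr, 0);
      Ytr.each_row() -= ybar;
      arma::mat P = H * Ytr;
      P.each_row() += ybar;
      preds[m] = P;
      fold_lambdas.push_back(lambda);
    }
  }

  const int ni = test_i.n_elem, nj = test_j.n_elem;
  for (size_t m = 0; m < n_models; ++m) {
    const arma::mat& Ym = Ytruth[m];
    const arma::mat& P = preds[m];
    if (same_target) {
      // all unordered pairs within one target's trials
      for (int i = 0; i < ni; ++i) {
        for (int j = i + 1; j < ni; ++j) {
          arma::rowvec pi = P.row(i), pj = P.row(j);
          arma::rowvec yi = Ym.row(test_i(i)), yj = Ym.row(test_i(j));
          rows[m].insert(rows[m].end(),
            { double(test_i(i) + 1), double(test_i(j) + 1),
              cos_dist(pi, yi), cos_dist(pj, yj),
              cos_dist(pi, yj), cos_dist(pj, yi) });
        }
      }
    } else {
      for (int i = 0; i < ni; ++i) {
        for (int j = 0; j < nj; ++j) {
          arma::rowvec pi = P.row(i), pj = P.row(ni + j);
          arma::rowvec yi = Ym.row(test_i(i)), yj = Ym.row(test_j(j));
          rows[m].insert(rows[m].end(),
            { double(test_i(i) + 1), double(test_j(j) + 1),
              cos_dist(pi, yi), cos_dist(pj, yj),
              cos_dist(pi, yj), cos_dist(pj, yi) });
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".l2o_single_gram")]]
List l2o_single_gram(const arma::mat& G, const List& Ys, const List& Ys_truth,
                     const arma::ivec& target, double lambda, bool use_gcv,
                     bool same_target_folds) {
  const int T = target.max();
  std::vector<arma::mat> Y(Ys.size()), Ytruth(Ys_truth.size());
  for (int m = 0; m < Ys.size(); ++m) Y[m] = as<arma::mat>(Ys[m]);
  for (int m = 0; m < Ys_truth.size(); ++m) Ytruth[m] = as<arma::mat>(Ys_truth[m]);
  std::vector<std::vector<double>> rows(Y.size());
  std::vector<double> fold_lambdas;

  std::vector<arma::uvec> by_target(T);
  for (int t = 0; t < T; ++t) by_target[t] = arma::find(target == t + 1);

  for (int a = 0; a < T; ++a) {
    for (int b = a + 1; b < T; ++b) {
      arma::uvec train = arma::find(target != a + 1 && target != b + 1);
      eval_fold(G, Y, Ytruth, train, by_target[a], by_target[b], false,
                lambda, use_gcv, rows, fold_lambdas);
    }
  }
  if (same_target_folds) {
    for (int a = 0; a < T; ++a) {
      arma::uvec train = arma::find(target != a + 1);
      eval_fold(G, Y, Ytruth, train, by_target[a], arma::uvec(), true,
                lambda, use_gcv, rows, fold_lambdas);
    }
  }

  List out(Y.size());
  for (size_t m = 0; m < Y.size(); ++m) {
    const size_t n_pairs = rows[m].size() / 6;
    NumericMatrix M(6, n_pairs);
    std::copy(rows[m].begin(), rows[m].end(), M.begin());
    out[m] = transpose(M);
  }
  out.attr("lambdas") = wrap(fold_lambdas);
  return out;
}
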