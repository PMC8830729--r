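#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// EM for the binomial admixture likelihood
//   L = sum_ij g_ij log(sum_k Q_ik F_kj) + (2 - g_ij) log(sum_k Q_ik (1-F_kj))
// over Q (n x K, rows simplex) and F (K x m, in [eps, 1-eps]).
// Missing genotypes are coded as a negative value and carry zero weight.
// The E step in matrix form: with P = Q F,
//   Ra = G / P,  Rb = (2 - G) / (1 - P)   (zeroed on missing entries)
//   A  = (Q' Ra) o F,  B = (Q' Rb) o (1 - F)      (expected allele counts)
//   F <- A / (A + B),  Q_ik <- Q o (Ra F' + Rb (1-F)') / (2 m_i)
// Q rows are re-projected onto the simplex every iteration: the frequency
// clipping otherwise lets row sums drift off 1 and the drift compounds.
// [[Rcpp::export]]
List em_admixture_cpp(const arma::imat& G, arma::mat Q, arma::mat F,
                      int max_iter, double tol, double eps) {
  const arma::uword n = G.n_rows, m = G.n_cols;
  arma::mat Gd = arma::conv_to<arma::mat>::from(G);
  arma::mat W = arma::conv_to<arma::mat>::from(G >= 0);
  Gd %= W;                               // missing -> 0 with zero weight
  arma::mat G2 = (2.0 - Gd) % W;
  arma::vec mobs = arma::sum(W, 1);      // observed loci per individual

  std::vector<double> ll_trace;
  ll_trace.reserve(std::min(max_iter, 4096));
  double ll_prev = -std::numeric_limits<double>::infinity();
  bool converged = false;

  for (int iter = 0; iter < max_iter; ++iter) {
    arma::mat P = Q * F;
    P.clamp(eps, 1.0 - eps);
    arma::mat Ra = Gd / P;
    arma::mat Rb = G2 / (1.0 - P);
    double ll = arma::accu(Gd % arma::log(P) + G2 % arma::log1p(-P));
    ll_trace.push_back(ll);
    if (iter > 0 && ll - ll_prev < tol) {
      converged = true;
      break;
    }
    ll_prev = ll;
    arma::mat A = (Q.t() * Ra) % F;                 // K x m
    arma::mat B = (Q.t() * Rb) % (1.0 - F);
    arma::mat Rq = Q % (Ra * F.t() + Rb * (1.0 - F.t()));   // n x K
    F = A / (A + B);
    F.replace(arma::datum::nan, 0.5);
    F.clamp(eps, 1.0 - eps);
    Rq.each_col() /= (2.0 * mobs);
    Rq.clamp(0.0, arma::datum::inf);
    arma::vec rs = arma::sum(Rq, 1);
    rs.replace(0.0, 1.0);
    Rq.each_col() /= rs;
    Q = Rq;
  }
  return List::create(_["Q"] = Q, _["F"] = F,
                      _["loglik"] = NumericVector(ll_trace.begin(), ll_trace.end()),
                      _["converged"] = converged);
}
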