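#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs core for the partially labeled topic model.
//
// Conventions (all 0-based in here; R wrappers convert):
//   - Extended labels 0..Lext-1; observed labels first, background (if any)
//     last.  Each extended label l owns the contiguous topic block
//     subset_start[l] .. subset_start[l] + subset_size[l] - 1.
//   - Tokens are stored document-major; sweeps visit them in that fixed
//     order.
//   - Randomness comes from R's RNG (unif_rand) so set.seed() on the R
//     side makes every run reproducible.

struct Counts {
  int D, Lext, K, W;
  std::vector<int> N_dl, N_lk, N_kw, N_d, N_l, N_k;
  Counts(int D_, int Lext_, int K_, int W_)
      : D(D_), Lext(Lext_), K(K_), W(W_),
        N_dl((size_t)D_ * Lext_, 0), N_lk((size_t)Lext_ * K_, 0),
        N_kw((size_t)K_ * W_, 0), N_d(D_, 0), N_l(Lext_, 0), N_k(K_, 0) {}
  inline int& dl(int d, int l) { return N_dl[(size_t)d * Lext + l]; }
  inline int& lk(int l, int k) { return N_lk[(size_t)l * K + k]; }
  inline int& kw(int k, int w) { return N_kw[(size_t)k * W + w]; }
  void add(int d, int l, int k, int w, int delta) {
    dl(d, l) += delta; lk(l, k) += delta; kw(k, w) += delta;
    N_d[d] += delta; N_l[l] += delta; N_k[k] += delta;
  }
};

// Unnormalized weight of candidate (l, k) for a token of word w in doc d,
// with the token itself already removed from the counts:
//   (beta + N_dl) * (alpha + N_lk) / (alpha*K_l + N_l)
//                 * (lambda + N_kw) / (lambda*W + N_k)
static inline double cand_weight(Counts& C, int d, int l, int k, int w,
                                 double alpha, double beta, double lambda,
                                 int Kl) {
  return (beta + C.dl(d, l)) *
         (alpha + C.lk(l, k)) / (alpha * Kl + C.N_l[l]) *
         (lambda + C.kw(k, w)) / (lambda * C.W + C.N_k[k]);
}

static inline int sample_cat(const std::vector<double>& w, double total) {
  double u = unif_rand() * total, c = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    c += w[i];
    if (u < c) return (int)i;
  }
  return (int)w.size() - 1;  // guard against rounding
}

// Collapsed log joint p(L, Z, W | Lambda, beta, alpha, lambda) up to the
// assignment-independent constant, restricted-support form.
static double log_joint(Counts& C, const std::vector<std::vector<int>>& act,
                        const IntegerVector& subset_start,
                        const IntegerVector& subset_size,
                        double alpha, double beta, double lambda) {
  double lj = 0.0;
  for (int d = 0; d < C.D; ++d) {
    int Ld = (int)act[d].size();
    lj += R::lgammafn(beta * Ld) - R::lgammafn(beta * Ld + C.N_d[d]);
    for (int l : act[d])
      lj += R::lgammafn(beta + C.dl(d, l)) - R::lgammafn(beta);
  }
  for (int l = 0; l < C.Lext; ++l) {
    int Kl = subset_size[l];
    lj += R::lgammafn(alpha * Kl) - R::lgammafn(alpha * Kl + C.N_l[l]);
    for (int j = 0; j < Kl; ++j) {
      int k = subset_start[l] + j;
      lj += R::lgammafn(alpha + C.lk(l, k)) - R::lgammafn(alpha);
    }
  }
  for (int k = 0; k < C.K; ++k) {
    lj += R::lgammafn(lambda * C.W) - R::lgammafn(lambda * C.W + C.N_k[k]);
    for (int w = 0; w < C.W; ++w)
      lj += R::lgammafn(lambda + C.kw(k, w)) - R::lgammafn(lambda);
  }
  return lj;
}

static std::vector<std::vector<int>> as_active(const List& doc_labels) {
  std::vector<std::vector<int>> act(doc_labels.size());
  for (R_xlen_t d = 0; d < doc_labels.size(); ++d) {
    IntegerVector a = doc_labels[d];
    act[d] = std::vector<int>(a.begin(), a.end());
  }
  return act;
}

// [[Rcpp::export]]
List pftp_gibbs_train_cpp(IntegerVector doc, IntegerVector word,
                          List doc_labels, IntegerVector subset_start,
                          IntegerVector subset_size, int D, int K, int W,
                          int Lext, double alpha, double beta, double lambda,
                          IntegerVector l0, IntegerVector z0, int iterations,
                          int burn_in, int thin, int log_every,
                          bool record_assignments, bool verbose) {
  const int N = doc.size();
  std::vector<std::vector<int>> act = as_active(doc_labels);
  Counts C(D, Lext, K, W);
  std::vector<int> la(l0.begin(), l0.end()), za(z0.begin(), z0.end());
  for (int n = 0; n < N; ++n) C.add(doc[n], la[n], za[n], word[n], +1);

  NumericMatrix pi_sum(Lext, K), theta_sum(K, W), psi_sum(D, Lext);
  int n_samples = 0;
  std::vector<double> lj_sweep, lj_val;
  IntegerMatrix trace_l, trace_z;
  if (record_assignments) {
    trace_l = IntegerMatrix(iterations, N);
    trace_z = IntegerMatrix(iterations, N);
  }

  std::vector<double> wgt;
  std::vector<int> cl, ck;
  RNGScope scope;
  for (int it = 1; it <= iterations; ++it) {
    for (int n = 0; n < N; ++n) {
      int d = doc[n], w = word[n];
      C.add(d, la[n], za[n], w, -1);
      wgt.clear(); cl.clear(); ck.clear();
      double total = 0.0;
      for (int l : act[d]) {
        int Kl = subset_size[l];
        for (int j = 0; j < Kl; ++j) {
          int k = subset_start[l] + j;
          double x = cand_weight(C, d, l, k, w, alpha, beta, lambda, Kl);
          wgt.push_back(x); cl.push_back(l); ck.push_back(k);
          total += x;
        }
      }
      int pick = sample_cat(wgt, total);
      la[n] = cl[pick]; za[n] = ck[pick];
      C.add(d, la[n], za[n], w, +1);
    }
    if (record_assignments)
      for (int n = 0; n < N; ++n) { trace_l(it - 1, n) = la[n]; trace_z(it - 1, n) = za[n]; }
    if (it > burn_in && (it - burn_in) % thin == 0) {
      ++n_samples;
      for (int d = 0; d < D; ++d) {
        double den = beta * (double)act[d].size() + C.N_d[d];
        for (int l : act[d]) psi_sum(d, l) += (beta + C.dl(d, l)) / den;
      }
      for (int l = 0; l < Lext; ++l) {
        int Kl = subset_size[l];
        double den = alpha * Kl + C.N_l[l];
        for (int j = 0; j < Kl; ++j) {
          int k = subset_start[l] + j;
          pi_sum(l, k) += (alpha + C.lk(l, k)) / den;
        }
      }
      for (int k = 0; k < K; ++k) {
        double den = lambda * W + C.N_k[k];
        for (int w = 0; w < W; ++w) theta_sum(k, w) += (lambda + C.kw(k, w)) / den;
      }
    }
    if (log_every > 0 && (it % log_every == 0 || it == iterations)) {
      double lj = log_joint(C, act, subset_start, subset_size, alpha, beta, lambda);
      lj_sweep.push_back(it); lj_val.push_back(lj);
      if (verbose)
        Rcout << "sweep " << it << "/" << iterations
              << " collapsed log-joint " << lj << "\n";
    }
    if (it % 64 == 0) checkUserInterrupt();
  }

  if (n_samples > 0) {
    pi_sum = pi_sum / (double)n_samples;
    theta_sum = theta_sum / (double)n_samples;
    psi_sum = psi_sum / (double)n_samples;
  }
  IntegerMatrix N_dl(D, Lext), N_lk(Lext, K), N_kw(K, W);
  for (int d = 0; d < D; ++d) for (int l = 0; l < Lext; ++l) N_dl(d, l) = C.dl(d, l);
  for (int l = 0; l < Lext; ++l) for (int k = 0; k < K; ++k) N_lk(l, k) = C.lk(l, k);
  for (int k = 0; k < K; ++k) for (int w = 0; w < W; ++w) N_kw(k, w) = C.kw(k, w);

  List out = List::create(
      _["l"] = IntegerVector(la.begin(), la.end()),
      _["z"] = IntegerVector(za.begin(), za.end()), _["N_dl"] = N_dl,
      _["N_lk"] = N_lk, _["N_kw"] = N_kw,
      _["N_d"] = IntegerVector(C.N_d.begin(), C.N_d.end()),
      _["N_l"] = IntegerVector(C.N_l.begin(), C.N_l.end()),
      _["N_k"] = IntegerVector(C.N_k.begin(), C.N_k.end()),
      _["pi_mean"] = pi_sum, _["theta_mean"] = theta_sum,
      _["psi_mean"] = psi_sum, _["n_samples"] = n_samples,
      _["log_joint"] = DataFrame::create(_["sweep"] = lj_sweep,
                                         _["log_joint"] = lj_val));
  if (record_assignments) { out["trace_l"] = trace_l; out["trace_z"] = trace_z; }
  return out;
}

// Normalized training conditional over the admissible (l, k) candidates of
// one token (counts passed in must already exclude the token).
// [[Rcpp::export]]
List pftp_cond_weights_cpp(IntegerMatrix N_dl, IntegerMatrix N_lk,
                           IntegerMatrix N_kw, IntegerVector N_l,
                           IntegerVector N_k, int d, int w,
                           IntegerVector active, IntegerVector subset_start,
                           IntegerVector subset_size, int W, double alpha,
                           double beta, double lambda) {
  std::vector<double> wgt; std::vector<int> cl, ck;
  double total = 0.0;
  for (int i = 0; i < active.size(); ++i) {
    int l = active[i], Kl = subset_size[l];
    for (int j = 0; j < Kl; ++j) {
      int k = subset_start[l] + j;
      double x = (beta + N_dl(d, l)) *
                 (alpha + N_lk(l, k)) / (alpha * Kl + N_l[l]) *
                 (lambda + N_kw(k, w)) / (lambda * W + N_k[k]);
      wgt.push_back(x); cl.push_back(l); ck.push_back(k); total += x;
    }
  }
  if (total <= 0) stop("all candidate weights are zero");
  NumericVector p(wgt.size());
  for (size_t i = 0; i < wgt.size(); ++i) p[i] = wgt[i] / total;
  return List::create(_["label"] = IntegerVector(cl.begin(), cl.end()),
                      _["topic"] = IntegerVector(ck.begin(), ck.end()),
                      _["prob"] = p);
}

// [[Rcpp::export]]
double pftp_log_joint_cpp(IntegerMatrix N_dl, IntegerMatrix N_lk,
                          IntegerMatrix N_kw, List doc_labels,
                          IntegerVector subset_start, IntegerVector subset_size,
                          double alpha, double beta, double lambda) {
  int D = N_dl.nrow(), Lext = N_dl.ncol(), K = N_kw.nrow(), W = N_kw.ncol();
  std::vector<std::vector<int>> act = as_active(doc_labels);
  Counts C(D, Lext, K, W);
  for (int d = 0; d < D; ++d)
    for (int l = 0; l < Lext; ++l) { C.dl(d, l) = N_dl(d, l); C.N_d[d] += N_dl(d, l); }
  for (int l = 0; l < Lext; ++l)
    for (int k = 0; k < K; ++k) { C.lk(l, k) = N_lk(l, k); C.N_l[l] += N_lk(l, k); }
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < W; ++w) { C.kw(k, w) = N_kw(k, w); C.N_k[k] += N_kw(k, w); }
  return log_joint(C, act, subset_start, subset_size, alpha, beta, lambda);
}

// Fold-in prediction: pi/theta frozen, every extended label admissible,
// only the per-document label counts are resampled.
// Candidate weight: (beta + N_dl) * pi(l, k) * theta(k, w).
// [[Rcpp::export]]
List pftp_gibbs_predict_cpp(IntegerVector doc, IntegerVector word,
                            NumericMatrix pi, NumericMatrix theta,
                            IntegerVector subset_start,
                            IntegerVector subset_size, int D, int Lext,
                            double beta, IntegerVector l0, IntegerVector z0,
                            int iterations, int burn_in, int thin) {
  const int N = doc.size();
  std::vector<int> la(l0.begin(), l0.end()), za(z0.begin(), z0.end());
  std::vector<int> N_dl((size_t)D * Lext, 0), N_d(D, 0);
  for (int n = 0; n < N; ++n) { N_dl[(size_t)doc[n] * Lext + la[n]]++; N_d[doc[n]]++; }

  NumericMatrix psi_sum(D, Lext);
  int n_samples = 0;
  std::vector<double> wgt; std::vector<int> cl, ck;
  RNGScope scope;
  for (int it = 1; it <= iterations; ++it) {
    for (int n = 0; n < N; ++n) {
      int d = doc[n], w = word[n];
      N_dl[(size_t)d * Lext + la[n]]--;
      wgt.clear(); cl.clear(); ck.clear();
      double total = 0.0;
      for (int l = 0; l < Lext; ++l) {
        double lab = beta + N_dl[(size_t)d * Lext + l];
        for (int j = 0; j < subset_size[l]; ++j) {
          int k = subset_start[l] + j;
          double x = lab * pi(l, k) * theta(k, w);
          wgt.push_back(x); cl.push_back(l); ck.push_back(k); total += x;
        }
      }
      int pick = sample_cat(wgt, total);
      la[n] = cl[pick]; za[n] = ck[pick];
      N_dl[(size_t)d * Lext + la[n]]++;
    }
    if (it > burn_in && (it - burn_in) % thin == 0) {
      ++n_samples;
      for (int d = 0; d < D; ++d) {
        double den = beta * Lext + N_d[d];
        for (int l = 0; l < Lext; ++l)
          psi_sum(d, l) += (beta + N_dl[(size_t)d * Lext + l]) / den;
      }
    }
    if (it % 64 == 0) checkUserInterrupt();
  }
  if (n_samples > 0) psi_sum = psi_sum / (double)n_samples;
  return List::create(_["psi_mean"] = psi_sum, _["n_samples"] = n_samples,
                      _["l"] = IntegerVector(la.begin(), la.end()),
                      _["z"] = IntegerVector(za.begin(), za.end()));
}
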