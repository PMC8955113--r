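#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// PV-DBOW with negative sampling: each graph is a "document" whose words
// are Weisfeiler-Lehman subtree labels; the document vector is trained to
// predict its words against noise words drawn from the unigram^0.75
// distribution. Deterministic given the seed (single-threaded, own RNG).

namespace {

inline double sigmoid(double x) {
  if (x > 10.0) return 1.0;
  if (x < -10.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

struct Sampler {
  std::mt19937 rng;
  std::vector<double> cum;  // cumulative unigram^0.75 mass

  Sampler(unsigned int seed, const std::vector<double>& counts)
      : rng(seed) {
    cum.resize(counts.size());
    double tot = 0.0;
    for (size_t i = 0; i < counts.size(); ++i) {
      tot += std::pow(counts[i], 0.75);
      cum[i] = tot;
    }
    for (size_t i = 0; i < cum.size(); ++i) cum[i] /= tot;
  }

  double unif() {
    return rng() * (1.0 / 4294967296.0);
  }

  int draw_word() {
    double u = unif();
    return static_cast<int>(
        std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
  }
};

// one SGD step for (doc vector d, word w, label), updating d and the
// word matrix row in place; returns nothing
inline void sgd_step(std::vector<double>& dvec, double* wrow, int k,
                     double label, double lr) {
  double dot = 0.0;
  for (int j = 0; j < k; ++j) dot += dvec[j] * wrow[j];
  double g = (label - sigmoid(dot)) * lr;
  for (int j = 0; j < k; ++j) {
    double dj = dvec[j];
    dvec[j] += g * wrow[j];
    wrow[j] += g * dj;
  }
}

// train one document vector against fixed or trainable word vectors
void train_doc(std::vector<double>& dvec, std::vector<double>& words,
               const std::vector<int>& tokens, int k, double lr,
               int negative, Sampler& smp, bool update_words) {
  std::vector<double> frozen_row(k);
  for (size_t t = 0; t < tokens.size(); ++t) {
    int w = tokens[t];
    double* wrow = &words[static_cast<size_t>(w) * k];
    if (update_words) {
      sgd_step(dvec, wrow, k, 1.0, lr);
    } else {
      std::copy(wrow, wrow + k, frozen_row.begin());
      sgd_step(dvec, frozen_row.data(), k, 1.0, lr);
    }
    for (int n = 0; n < negative; ++n) {
      int wn = smp.draw_word();
      if (wn == w) continue;
      double* nrow = &words[static_cast<size_t>(wn) * k];
      if (update_words) {
        sgd_step(dvec, nrow, k, 0.0, lr);
      } else {
        std::copy(nrow, nrow + k, frozen_row.begin());
        sgd_step(dvec, frozen_row.data(), k, 0.0, lr);
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List pvdbow_train_cpp(List tokens_list, int vocab_size, int k, int epochs,
                      double lr, int negative, int seed) {
  int n_docs = tokens_list.size();
  std::vector<std::vector<int>> docs(n_docs);
  std::vector<double> counts(vocab_size, 0.0);
  for (int d = 0; d < n_docs; ++d) {
    IntegerVector tv = tokens_list[d];
    docs[d].assign(tv.begin(), tv.end());
    for (int w : docs[d]) counts[w] += 1.0;
  }
  for (int w = 0; w < vocab_size; ++w) {
    if (counts[w] == 0.0) counts[w] = 1e-12;  // keep sampler well defined
  }
  Sampler smp(static_cast<unsigned int>(seed), counts);

  std::vector<std::vector<double>> dvecs(n_docs, std::vector<double>(k));
  for (int d = 0; d < n_docs; ++d) {
    for (int j = 0; j < k; ++j) {
      dvecs[d][j] = (smp.unif() - 0.5) / k;
    }
  }
  std::vector<double> words(static_cast<size_t>(vocab_size) * k, 0.0);

  for (int e = 0; e < epochs; ++e) {
    double lr_e = lr * (1.0 - static_cast<double>(e) / epochs);
    if (lr_e < lr * 1e-4) lr_e = lr * 1e-4;
    // visit documents in a fresh seeded order each epoch
    std::vector<int> order(n_docs);
    for (int d = 0; d < n_docs; ++d) order[d] = d;
    std::shuffle(order.begin(), order.end(), smp.rng);
    for (int d : order) {
      train_doc(dvecs[d], words, docs[d], k, lr_e, negative, smp, true);
    }
  }

  NumericMatrix doc_mat(n_docs, k);
  for (int d = 0; d < n_docs; ++d) {
    for (int j = 0; j < k; ++j) doc_mat(d, j) = dvecs[d][j];
  }
  NumericMatrix word_mat(vocab_size, k);
  for (int w = 0; w < vocab_size; ++w) {
    for (int j = 0; j < k; ++j) {
      word_mat(w, j) = words[static_cast<size_t>(w) * k + j];
    }
  }
  return List::create(_["doc_vectors"] = doc_mat,
                      _["word_vectors"] = word_mat,
                      _["counts"] = NumericVector(counts.begin(),
                                                  counts.end()));
}

// [[Rcpp::export]]
NumericVector pvdbow_infer_cpp(IntegerVector tokens, NumericMatrix word_mat,
                               NumericVector counts, int epochs, double lr,
                               int negative, int seed) {
  int k = word_mat.ncol();
  int vocab_size = word_mat.nrow();
  std::vector<double> cnt(counts.begin(), counts.end());
  Sampler smp(static_cast<unsigned int>(seed), cnt);
  std::vector<double> dvec(k);
  for (int j = 0; j < k; ++j) dvec[j] = (smp.unif() - 0.5) / k;
  if (tokens.size() == 0) {
    return NumericVector(k, 0.0);  // no structure: zero-information vector
  }
  std::vector<double> words(static_cast<size_t>(vocab_size) * k);
  for (int w = 0; w < vocab_size; ++w) {
    for (int j = 0; j < k; ++j) {
      words[static_cast<size_t>(w) * k + j] = word_mat(w, j);
    }
  }
  std::vector<int> toks(tokens.begin(), tokens.end());
  for (int e = 0; e < epochs; ++e) {
    double lr_e = lr * (1.0 - static_cast<double>(e) / epochs);
    if (lr_e < lr * 1e-4) lr_e = lr * 1e-4;
    train_doc(dvec, words, toks, k, lr_e, negative, smp, false);
  }
  return NumericVector(dvec.begin(), dvec.end());
}
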