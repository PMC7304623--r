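// Hierarchical LSTM document classifier.
//
// A word-level LSTM encodes each sentence's (frozen) embedded token
// sequence into its final hidden state; a sentence-level LSTM encodes the
// resulting sentence-vector sequence into a document vector; an affine +
// logistic head emits the class probability. Trained by mini-batch Adam
// on log-loss with global-norm gradient clipping. All randomness
// (initialisation, epoch shuffling) comes from one seeded mt19937, and
// computation is single-threaded, so runs are reproducible bit-for-bit.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

typedef std::vector<std::vector<std::vector<int> > > DocSet;

static DocSet convert_docs(List docs) {
  DocSet out(docs.size());
  for (int d = 0; d < docs.size(); ++d) {
    List sents = docs[d];
    out[d].resize(sents.size());
    for (int s = 0; s < sents.size(); ++s) {
      IntegerVector iv = sents[s];
      out[d][s].assign(iv.begin(), iv.end());
    }
  }
  return out;
}

struct LSTMParams {
  mat Wx, Wh;  // (4H x E), (4H x H)
  vec b;       // 4H
};

struct LSTMCache {
  mat X;                 // T x E inputs
  mat I, F, O, G, C, H;  // T x H gate/state activations
};

static inline vec sigm(const vec& z) { return 1.0 / (1.0 + arma::exp(-z)); }

// Forward pass; returns final hidden state, filling the cache.
static vec lstm_forward(const mat& X, const LSTMParams& p, LSTMCache& cc) {
  const int T = X.n_rows, H = p.Wh.n_cols;
  cc.X = X;
  cc.I.set_size(T, H); cc.F.set_size(T, H); cc.O.set_size(T, H);
  cc.G.set_size(T, H); cc.C.set_size(T, H); cc.H.set_size(T, H);
  vec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    vec a = p.Wx * X.row(t).t() + p.Wh * h + p.b;
    vec i = sigm(a.subvec(0, H - 1));
    vec f = sigm(a.subvec(H, 2 * H - 1));
    vec o = sigm(a.subvec(2 * H, 3 * H - 1));
    vec g = arma::tanh(a.subvec(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    cc.I.row(t) = i.t(); cc.F.row(t) = f.t(); cc.O.row(t) = o.t();
    cc.G.row(t) = g.t(); cc.C.row(t) = c.t(); cc.H.row(t) = h.t();
  }
  return h;
}

// Backward pass with gradient only at the final hidden state. Accumulates
// into dWx/dWh/db; optionally returns gradients w.r.t. the inputs.
static void lstm_backward(const LSTMCache& cc, const LSTMParams& p,
                          const vec& dh_final, mat& dWx, mat& dWh, vec& db,
                          mat* dX) {
  const int T = cc.X.n_rows, H = p.Wh.n_cols;
  if (dX) dX->zeros(T, cc.X.n_cols);
  vec dh = dh_final, dc(H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec i = cc.I.row(t).t(), f = cc.F.row(t).t(), o = cc.O.row(t).t(),
        g = cc.G.row(t).t(), c = cc.C.row(t).t();
    vec c_prev = (t > 0) ? vec(cc.C.row(t - 1).t()) : vec(H, arma::fill::zeros);
    vec h_prev = (t > 0) ? vec(cc.H.row(t - 1).t()) : vec(H, arma::fill::zeros);
    vec tc = arma::tanh(c);
    vec do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    vec di = dc % g, dg = dc % i, df = dc % c_prev;
    vec dc_prev = dc % f;
    vec da(4 * H);
    da.subvec(0, H - 1)         = di % i % (1.0 - i);
    da.subvec(H, 2 * H - 1)     = df % f % (1.0 - f);
    da.subvec(2 * H, 3 * H - 1) = do_ % o % (1.0 - o);
    da.subvec(3 * H, 4 * H - 1) = dg % (1.0 - g % g);
    dWx += da * cc.X.row(t);
    dWh += da * h_prev.t();
    db += da;
    if (dX) dX->row(t) = (p.Wx.t() * da).t();
    dh = p.Wh.t() * da;
    dc = dc_prev;
  }
}

struct Model {
  LSTMParams word, sent;
  vec v;       // head weights (Hs)
  double c0;   // head bias
};

// Forward a whole document; sentence caches are filled for backprop.
static double doc_forward(const std::vector<std::vector<int> >& doc,
                          const mat& emb, const Model& m,
                          std::vector<LSTMCache>& wcaches, LSTMCache& scache,
                          mat& SV, vec& hdoc) {
  const int Hw = m.word.Wh.n_cols, Hs = m.sent.Wh.n_cols;
  int S = doc.size();
  wcaches.assign(S, LSTMCache());
  SV.set_size(S, Hw);
  for (int s = 0; s < S; ++s) {
    const std::vector<int>& idx = doc[s];
    mat X(idx.size(), emb.n_cols);
    for (size_t t = 0; t < idx.size(); ++t) X.row(t) = emb.row(idx[t] - 1);
    SV.row(s) = lstm_forward(X, m.word, wcaches[s]).t();
  }
  if (S > 0) {
    hdoc = lstm_forward(SV, m.sent, scache);
  } else {
    hdoc = vec(Hs, arma::fill::zeros);
  }
  double z = arma::dot(m.v, hdoc) + m.c0;
  return 1.0 / (1.0 + std::exp(-z));
}

struct Grads {
  mat dWxw, dWhw, dWxs, dWhs;
  vec dbw, dbs, dv;
  double dc0;
  void zero(const Model& m) {
    dWxw.zeros(arma::size(m.word.Wx)); dWhw.zeros(arma::size(m.word.Wh));
    dbw.zeros(m.word.b.n_elem);
    dWxs.zeros(arma::size(m.sent.Wx)); dWhs.zeros(arma::size(m.sent.Wh));
    dbs.zeros(m.sent.b.n_elem);
    dv.zeros(m.v.n_elem); dc0 = 0.0;
  }
};

static void doc_backward(const std::vector<std::vector<int> >& doc,
                         const Model& m, std::vector<LSTMCache>& wcaches,
                         LSTMCache& scache, const mat& SV, const vec& hdoc,
                         double p, double y, Grads& g) {
  double dz = p - y;
  g.dv += dz * hdoc;
  g.dc0 += dz;
  int S = doc.size();
  if (S == 0) return;
  vec dhdoc = dz * m.v;
  mat dSV;
  lstm_backward(scache, m.sent, dhdoc, g.dWxs, g.dWhs, g.dbs, &dSV);
  for (int s = 0; s < S; ++s) {
    lstm_backward(wcaches[s], m.word, dSV.row(s).t(), g.dWxw, g.dWhw, g.dbw,
                  nullptr);
  }
}

static Model init_model(int E, int Hw, int Hs, std::mt19937& rng) {
  std::uniform_real_distribution<double> u(-0.08, 0.08);
  Model m;
  m.word.Wx.set_size(4 * Hw, E); m.word.Wh.set_size(4 * Hw, Hw);
  m.word.b = vec(4 * Hw, arma::fill::zeros);
  m.sent.Wx.set_size(4 * Hs, Hw); m.sent.Wh.set_size(4 * Hs, Hs);
  m.sent.b = vec(4 * Hs, arma::fill::zeros);
  m.v.set_size(Hs);
  for (auto* M : {&m.word.Wx, &m.word.Wh, &m.sent.Wx, &m.sent.Wh}) {
    for (arma::uword k = 0; k < M->n_elem; ++k) (*M)(k) = u(rng);
  }
  for (arma::uword k = 0; k < m.v.n_elem; ++k) m.v(k) = u(rng);
  // positive forget-gate bias keeps early gradients flowing
  m.word.b.subvec(Hw, 2 * Hw - 1).fill(1.0);
  m.sent.b.subvec(Hs, 2 * Hs - 1).fill(1.0);
  m.c0 = 0.0;
  return m;
}

static List model_to_list(const Model& m) {
  return List::create(
      _["word_Wx"] = wrap(m.word.Wx), _["word_Wh"] = wrap(m.word.Wh),
      _["word_b"] = wrap(m.word.b), _["sent_Wx"] = wrap(m.sent.Wx),
      _["sent_Wh"] = wrap(m.sent.Wh), _["sent_b"] = wrap(m.sent.b),
      _["head_v"] = wrap(m.v), _["head_b"] = m.c0);
}

static Model model_from_list(List L) {
  Model m;
  m.word.Wx = as<mat>(L["word_Wx"]); m.word.Wh = as<mat>(L["word_Wh"]);
  m.word.b = as<vec>(L["word_b"]);
  m.sent.Wx = as<mat>(L["sent_Wx"]); m.sent.Wh = as<mat>(L["sent_Wh"]);
  m.sent.b = as<vec>(L["sent_b"]);
  m.v = as<vec>(L["head_v"]); m.c0 = as<double>(L["head_b"]);
  return m;
}

// [[Rcpp::export]]
List rnn_train_cpp(List docs, arma::mat emb, NumericVector y,
                   int word_hidden, int sent_hidden, int epochs, int batch,
                   double lr, double clip, int seed) {
  DocSet ds = convert_docs(docs);
  const int n = ds.size();
  if (n == 0) stop("empty corpus");
  std::mt19937 rng((unsigned)seed);
  Model m = init_model(emb.n_cols, word_hidden, sent_hidden, rng);

  // Adam state, one slot per parameter group
  Grads g, adam_m, adam_v;
  adam_m.zero(m); adam_v.zero(m);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  NumericVector loss_history(epochs);

  std::vector<LSTMCache> wcaches;
  LSTMCache scache;
  mat SV;
  vec hdoc;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double total = 0.0;
    for (int start = 0; start < n; start += batch) {
      int stop_ = std::min(n, start + batch);
      g.zero(m);
      for (int o = start; o < stop_; ++o) {
        int d = order[o];
        double p = doc_forward(ds[d], emb, m, wcaches, scache, SV, hdoc);
        p = std::min(1.0 - 1e-12, std::max(1e-12, p));
        total += -(y[d] * std::log(p) + (1.0 - y[d]) * std::log(1.0 - p));
        doc_backward(ds[d], m, wcaches, scache, SV, hdoc, p, y[d], g);
      }
      double bs = (double)(stop_ - start);
      std::vector<mat*> gs = {&g.dWxw, &g.dWhw, &g.dWxs, &g.dWhs};
      std::vector<vec*> gv = {&g.dbw, &g.dbs, &g.dv};
      double nrm2 = g.dc0 * g.dc0;
      for (auto* M : gs) { *M /= bs; nrm2 += arma::accu(arma::square(*M)); }
      for (auto* V : gv) { *V /= bs; nrm2 += arma::accu(arma::square(*V)); }
      g.dc0 /= bs;
      nrm2 = std::sqrt(nrm2);
      if (nrm2 > clip) {
        double sc = clip / nrm2;
        for (auto* M : gs) *M *= sc;
        for (auto* V : gv) *V *= sc;
        g.dc0 *= sc;
      }
      ++step;
      double corr = lr * std::sqrt(1.0 - std::pow(b2, (double)step)) /
                    (1.0 - std::pow(b1, (double)step));
      std::vector<mat*> ps = {&m.word.Wx, &m.word.Wh, &m.sent.Wx, &m.sent.Wh};
      std::vector<mat*> ms = {&adam_m.dWxw, &adam_m.dWhw, &adam_m.dWxs, &adam_m.dWhs};
      std::vector<mat*> vs = {&adam_v.dWxw, &adam_v.dWhw, &adam_v.dWxs, &adam_v.dWhs};
      for (size_t q = 0; q < ps.size(); ++q) {
        *ms[q] = b1 * (*ms[q]) + (1 - b1) * (*gs[q]);
        *vs[q] = b2 * (*vs[q]) + (1 - b2) * arma::square(*gs[q]);
        *ps[q] -= corr * (*ms[q]) / (arma::sqrt(*vs[q]) + eps);
      }
      std::vector<vec*> pv = {&m.word.b, &m.sent.b, &m.v};
      std::vector<vec*> mv = {&adam_m.dbw, &adam_m.dbs, &adam_m.dv};
      std::vector<vec*> vv = {&adam_v.dbw, &adam_v.dbs, &adam_v.dv};
      for (size_t q = 0; q < pv.size(); ++q) {
        *mv[q] = b1 * (*mv[q]) + (1 - b1) * (*gv[q]);
        *vv[q] = b2 * (*vv[q]) + (1 - b2) * arma::square(*gv[q]);
        *pv[q] -= corr * (*mv[q]) / (arma::sqrt(*vv[q]) + eps);
      }
      adam_m.dc0 = b1 * adam_m.dc0 + (1 - b1) * g.dc0;
      adam_v.dc0 = b2 * adam_v.dc0 + (1 - b2) * g.dc0 * g.dc0;
      m.c0 -= corr * adam_m.dc0 / (std::sqrt(adam_v.dc0) + eps);
    }
    loss_history[ep] = total / n;
    if (!std::isfinite(loss_history[ep]))
      stop("non-finite training loss at epoch %d", ep + 1);
  }
  List out = model_to_list(m);
  out["loss_history"] = loss_history;
  return out;
}

// [[Rcpp::export]]
NumericVector rnn_predict_cpp(List docs, arma::mat emb, List params) {
  DocSet ds = convert_docs(docs);
  Model m = model_from_list(params);
  NumericVector out(ds.size());
  std::vector<LSTMCache> wcaches;
  LSTMCache scache;
  mat SV;
  vec hdoc;
  for (size_t d = 0; d < ds.size(); ++d) {
    out[d] = doc_forward(ds[d], emb, m, wcaches, scache, SV, hdoc);
  }
  return out;
}

// Numerical-check helper: loss and flattened analytic gradient for one
// document, used by the test suite to validate backpropagation against
// finite differences.
// [[Rcpp::export]]
List rnn_loss_grad_cpp(List doc, arma::mat emb, List params, double y) {
  DocSet ds = convert_docs(List::create(doc));
  Model m = model_from_list(params);
  std::vector<LSTMCache> wcaches;
  LSTMCache scache;
  mat SV;
  vec hdoc;
  double p = doc_forward(ds[0], emb, m, wcaches, scache, SV, hdoc);
  p = std::min(1.0 - 1e-12, std::max(1e-12, p));
  double loss = -(y * std::log(p) + (1.0 - y) * std::log(1.0 - p));
  Grads g;
  g.zero(m);
  doc_backward(ds[0], m, wcaches, scache, SV, hdoc, p, y, g);
  return List::create(
      _["loss"] = loss,
      _["grad"] = List::create(
          _["word_Wx"] = wrap(g.dWxw), _["word_Wh"] = wrap(g.dWhw),
          _["word_b"] = wrap(g.dbw), _["sent_Wx"] = wrap(g.dWxs),
          _["sent_Wh"] = wrap(g.dWhs), _["sent_b"] = wrap(g.dbs),
          _["head_v"] = wrap(g.dv), _["head_b"] = g.dc0));
}
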