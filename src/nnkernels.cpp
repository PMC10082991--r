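// Hot numeric kernels: the stacked-LSTM weighted-gradient pass (teacher
// forcing with per-position loss weights, shared by likelihood training and
// REINFORCE) and the batched sampling continuation used by Monte-Carlo
// rollouts. All randomness is supplied by the caller as pre-drawn uniforms
// so the R-level RNG seed governs every stochastic path.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static inline arma::mat sigmoid(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// Gate order along the 4H axis: input, forget, candidate, output.
struct CellOut {
  arma::mat i, f, g, o, c, h;
};

static CellOut lstmCell(const arma::mat& W, const arma::mat& U,
                        const arma::vec& b, const arma::mat& x,
                        const arma::mat& hPrev, const arma::mat& cPrev) {
  const arma::uword H = hPrev.n_cols;
  arma::mat z = x * W + hPrev * U;
  z.each_row() += b.t();
  CellOut out;
  out.i = sigmoid(z.cols(0, H - 1));
  out.f = sigmoid(z.cols(H, 2 * H - 1));
  out.g = arma::tanh(z.cols(2 * H, 3 * H - 1));
  out.o = sigmoid(z.cols(3 * H, 4 * H - 1));
  out.c = out.f % cPrev + out.i % out.g;
  out.h = out.o % arma::tanh(out.c);
  return out;
}

// Gradient of  L = -sum_{b,t} weights(b,t) * log p(target_bt | prefix)
// for a stacked LSTM language model under teacher forcing.
// ids: B x T (1-based token ids), weights: B x (T-1).
// dropMasks (optional): B x (L*H) x (T-1) cube of inverted-dropout masks
// applied to each layer's output (the top layer's mask gates the softmax
// input as well).
// [[Rcpp::export(name = ".cppLstmGrad")]]
List cppLstmGrad(const arma::mat& E, const List& layers, const arma::mat& M,
                 const arma::vec& cvec, const arma::imat& ids,
                 const arma::mat& weights, Nullable<NumericVector> dropMasks) {
  const arma::uword B = ids.n_rows;
  const arma::uword Tin = ids.n_cols - 1;
  const arma::uword L = layers.size();
  const arma::uword V = E.n_rows;
  const arma::uword H = M.n_rows;

  std::vector<arma::mat> Ws(L), Us(L);
  std::vector<arma::vec> bs(L);
  for (arma::uword l = 0; l < L; ++l) {
    List lay = layers[l];
    Ws[l] = as<arma::mat>(lay["W"]);
    Us[l] = as<arma::mat>(lay["U"]);
    bs[l] = as<arma::vec>(lay["b"]);
  }

  bool useDrop = dropMasks.isNotNull();
  arma::cube masks;
  if (useDrop) {
    NumericVector mv(dropMasks.get());
    IntegerVector dims = mv.attr("dim");
    masks = arma::cube(mv.begin(), dims[0], dims[1], dims[2], true);
  }

  // forward, caching per step and layer
  std::vector<std::vector<CellOut>> cache(Tin,
                                          std::vector<CellOut>(L));
  std::vector<std::vector<arma::mat>> xin(Tin,
                                          std::vector<arma::mat>(L));
  std::vector<arma::mat> hTop(Tin), probs(Tin);
  arma::mat logProbTargets(B, Tin, arma::fill::zeros);
  std::vector<arma::mat> hPrev(L, arma::mat(B, H, arma::fill::zeros));
  std::vector<arma::mat> cPrev(L, arma::mat(B, H, arma::fill::zeros));

  for (arma::uword t = 0; t < Tin; ++t) {
    arma::mat x(B, E.n_cols);
    for (arma::uword b = 0; b < B; ++b)
      x.row(b) = E.row(ids(b, t) - 1);
    for (arma::uword l = 0; l < L; ++l) {
      xin[t][l] = x;
      CellOut cell = lstmCell(Ws[l], Us[l], bs[l], x, hPrev[l], cPrev[l]);
      cache[t][l] = cell;
      hPrev[l] = cell.h;
      cPrev[l] = cell.c;
      x = cell.h;
      if (useDrop)
        x %= masks.slice(t).cols(l * H, (l + 1) * H - 1);
    }
    hTop[t] = x;
    arma::mat logits = x * M;
    logits.each_row() += cvec.t();
    arma::vec mx = arma::max(logits, 1);
    logits.each_col() -= mx;
    arma::mat ex = arma::exp(logits);
    arma::vec se = arma::sum(ex, 1);
    probs[t] = ex.each_col() / se;
    for (arma::uword b = 0; b < B; ++b)
      logProbTargets(b, t) =
        logits(b, ids(b, t + 1) - 1) - std::log(se(b));
  }

  // backward
  arma::mat gE(V, E.n_cols, arma::fill::zeros);
  arma::mat gM(H, V, arma::fill::zeros);
  arma::vec gc(V, arma::fill::zeros);
  std::vector<arma::mat> gW(L), gU(L);
  std::vector<arma::vec> gb(L);
  for (arma::uword l = 0; l < L; ++l) {
    gW[l] = arma::mat(arma::size(Ws[l]), arma::fill::zeros);
    gU[l] = arma::mat(arma::size(Us[l]), arma::fill::zeros);
    gb[l] = arma::vec(4 * H, arma::fill::zeros);
  }
  std::vector<arma::mat> dhNext(L, arma::mat(B, H, arma::fill::zeros));
  std::vector<arma::mat> dcNext(L, arma::mat(B, H, arma::fill::zeros));

  for (arma::sword ts = Tin - 1; ts >= 0; --ts) {
    arma::uword t = ts;
    arma::mat D = probs[t];
    D.each_col() %= weights.col(t);
    for (arma::uword b = 0; b < B; ++b)
      D(b, ids(b, t + 1) - 1) -= weights(b, t);
    gM += hTop[t].t() * D;
    gc += arma::sum(D, 0).t();
    arma::mat dAbove = D * M.t();
    for (arma::sword ls = L - 1; ls >= 0; --ls) {
      arma::uword l = ls;
      if (useDrop)
        dAbove %= masks.slice(t).cols(l * H, (l + 1) * H - 1);
      const CellOut& cc = cache[t][l];
      arma::mat dh = dhNext[l] + dAbove;
      arma::mat tc = arma::tanh(cc.c);
      arma::mat dout = dh % tc;
      arma::mat dc = dcNext[l] + dh % cc.o % (1.0 - tc % tc);
      arma::mat cpm(B, H, arma::fill::zeros);
      arma::mat hpm(B, H, arma::fill::zeros);
      if (t > 0) {
        cpm = cache[t - 1][l].c;
        hpm = cache[t - 1][l].h;
      }
      arma::mat di = dc % cc.g;
      arma::mat df = dc % cpm;
      dcNext[l] = dc % cc.f;
      arma::mat dz(B, 4 * H);
      dz.cols(0, H - 1) = di % cc.i % (1.0 - cc.i);
      dz.cols(H, 2 * H - 1) = df % cc.f % (1.0 - cc.f);
      dz.cols(2 * H, 3 * H - 1) = (dc % cc.i) % (1.0 - cc.g % cc.g);
      dz.cols(3 * H, 4 * H - 1) = dout % cc.o % (1.0 - cc.o);
      gW[l] += xin[t][l].t() * dz;
      gU[l] += hpm.t() * dz;
      gb[l] += arma::sum(dz, 0).t();
      dhNext[l] = dz * Us[l].t();
      dAbove = dz * Ws[l].t();
    }
    for (arma::uword b = 0; b < B; ++b)
      gE.row(ids(b, t) - 1) += dAbove.row(b);
  }

  List gLayers(L);
  for (arma::uword l = 0; l < L; ++l)
    gLayers[l] = List::create(Named("W") = gW[l], Named("U") = gU[l],
                              Named("b") = gb[l]);
  return List::create(
    Named("logProbTargets") = logProbTargets,
    Named("grads") = List::create(Named("E") = gE, Named("layers") = gLayers,
                                  Named("M") = gM, Named("cvec") = gc));
}

// Batched ancestral continuation: starting from per-layer states (already
// having consumed the prefix), repeatedly emit a token from the softmax
// head and feed it back, freezing rows at their first end token or at
// their per-row step limit (rows from different cut positions share one
// batch). uniforms: B x nSteps pre-drawn U(0,1). Returns the emitted
// tokens (pad after a row's end) and optionally the per-step states.
// [[Rcpp::export(name = ".cppLstmContinue")]]
List cppLstmContinue(const arma::mat& E, const List& layers,
                     const arma::mat& M, const arma::vec& cvec,
                     const arma::cube& h0, const arma::cube& c0,
                     const arma::mat& uniforms, int nSteps,
                     int endId, int padId, bool keepStates,
                     const arma::ivec& limits) {
  const arma::uword B = h0.n_rows;
  const arma::uword H = h0.n_cols;
  const arma::uword L = layers.size();
  std::vector<arma::mat> Ws(L), Us(L);
  std::vector<arma::vec> bs(L);
  for (arma::uword l = 0; l < L; ++l) {
    List lay = layers[l];
    Ws[l] = as<arma::mat>(lay["W"]);
    Us[l] = as<arma::mat>(lay["U"]);
    bs[l] = as<arma::vec>(lay["b"]);
  }
  std::vector<arma::mat> h(L), c(L), WU(L);
  for (arma::uword l = 0; l < L; ++l) {
    h[l] = h0.slice(l);
    c[l] = c0.slice(l);
    WU[l] = arma::join_cols(Ws[l], Us[l]);  // fused input+recurrent GEMM
  }
  arma::imat tokens(B, nSteps);
  tokens.fill(padId);
  List stateList(keepStates ? nSteps : 0);
  int emitted = 0;
  std::vector<bool> done(B, false);
  // rows still generating; compacted away once finished (unless per-step
  // states are requested, which requires the full batch layout)
  arma::uvec map = arma::regspace<arma::uvec>(0, B - 1);
  for (int s = 0; s < nSteps; ++s) {
    const arma::uword R = map.n_elem;
    arma::mat ex = h[L - 1] * M;
    ex.each_row() += cvec.t();
    arma::vec mx = arma::max(ex, 1);
    ex.each_col() -= mx;
    ex = arma::exp(ex);
    arma::vec se = arma::sum(ex, 1);
    arma::ivec tok(R);
    arma::uword nAlive = 0;
    // inverse-CDF draw, sweeping columns (cache-friendly for column-major)
    arma::vec acc(R, arma::fill::zeros);
    arma::vec thr(R);
    for (arma::uword r = 0; r < R; ++r) {
      tok(r) = 0;
      if (s >= limits(map(r))) done[map(r)] = true;
      thr(r) = done[map(r)] ? -1.0 : uniforms(map(r), s) * se(r);
    }
    const arma::uword V = ex.n_cols;
    for (arma::uword v = 0; v < V; ++v) {
      const double* col = ex.colptr(v);
      for (arma::uword r = 0; r < R; ++r) {
        if (tok(r) == 0 && thr(r) >= 0.0) {
          acc(r) += col[r];
          if (acc(r) >= thr(r) || v == V - 1) tok(r) = (int)v + 1;
        }
      }
    }
    for (arma::uword r = 0; r < R; ++r) {
      if (thr(r) < 0.0) { tok(r) = padId; continue; }
      tokens(map(r), s) = tok(r);
      if (tok(r) == endId) done[map(r)] = true; else ++nAlive;
    }
    emitted = s + 1;
    if (nAlive == 0 && !keepStates) break;
    // advance states (frozen rows consume pad; their state is unused)
    arma::mat x(R, E.n_cols);
    for (arma::uword r = 0; r < R; ++r)
      x.row(r) = E.row(tok(r) - 1);
    for (arma::uword l = 0; l < L; ++l) {
      arma::mat z = arma::join_rows(x, h[l]) * WU[l];
      z.each_row() += bs[l].t();
      z.cols(0, 2 * H - 1).transform(
        [](double v) { return 1.0 / (1.0 + std::exp(-v)); });
      z.cols(2 * H, 3 * H - 1).transform(
        [](double v) { return std::tanh(v); });
      z.cols(3 * H, 4 * H - 1).transform(
        [](double v) { return 1.0 / (1.0 + std::exp(-v)); });
      c[l] = z.cols(H, 2 * H - 1) % c[l] +
             z.cols(0, H - 1) % z.cols(2 * H, 3 * H - 1);
      h[l] = z.cols(3 * H, 4 * H - 1) % arma::tanh(c[l]);
      x = h[l];
    }
    if (keepStates) {
      arma::cube hs(B, H, L), cs(B, H, L);
      for (arma::uword l = 0; l < L; ++l) {
        hs.slice(l) = h[l];
        cs.slice(l) = c[l];
      }
      stateList[s] = List::create(Named("h") = hs, Named("c") = cs);
      if (nAlive == 0) break;
      continue;
    }
    if (nAlive == 0) break;
    if (nAlive < (R * 3) / 5) {
      arma::uvec keep(nAlive);
      arma::uword k2 = 0;
      for (arma::uword r = 0; r < R; ++r)
        if (!done[map(r)]) keep(k2++) = r;
      map = map(keep);
      for (arma::uword l = 0; l < L; ++l) {
        h[l] = h[l].rows(keep);
        c[l] = c[l].rows(keep);
      }
    }
  }
  return List::create(Named("tokens") = tokens,
                      Named("emitted") = emitted,
                      Named("states") = stateList);
}

// Forward-only discriminator scoring: embed, multiscale convolution, ReLU,
// max-pool over windows that fit inside each row's token stream (up to the
// first end token, or the full width when a row has none), concatenate,
// linear head, logistic. ids: B x T (1-based).
// [[Rcpp::export(name = ".cppDiscScore")]]
arma::vec cppDiscScore(const arma::mat& E, const List& conv,
                       const arma::ivec& windows, const arma::vec& headW,
                       double headB, const arma::imat& ids, int endId) {
  const arma::uword B = ids.n_rows;
  const arma::uword T = ids.n_cols;
  const arma::uword k = E.n_cols;
  arma::ivec lens(B);
  for (arma::uword b = 0; b < B; ++b) {
    lens(b) = T;
    for (arma::uword t = 0; t < T; ++t)
      if (ids(b, t) == endId) { lens(b) = t + 1; break; }
  }
  // embedded rows per position
  std::vector<arma::mat> At(T);
  for (arma::uword t = 0; t < T; ++t) {
    arma::mat x(B, k);
    for (arma::uword b = 0; b < B; ++b)
      x.row(b) = E.row(ids(b, t) - 1);
    At[t] = x;
  }
  arma::vec logit(B, arma::fill::value(headB));
  arma::uword off = 0;
  for (arma::uword wi = 0; wi < (arma::uword)windows.n_elem; ++wi) {
    const arma::uword l = windows(wi);
    List bank = conv[wi];
    arma::mat W = as<arma::mat>(bank["W"]);   // (l*k) x F
    arma::vec bb = as<arma::vec>(bank["b"]);
    const arma::uword F = W.n_cols;
    if (l > T) { off += F; continue; }
    const arma::uword P = T - l + 1;
    arma::mat Z(B * P, l * k);
    for (arma::uword j = 0; j < l; ++j)
      for (arma::uword p = 0; p < P; ++p)
        Z.submat(p * B, j * k, (p + 1) * B - 1, (j + 1) * k - 1) =
          At[p + j];
    arma::mat C = Z * W;
    C.each_row() += bb.t();
    C.transform([](double v) { return v > 0.0 ? v : 0.0; });
    arma::mat pool(B, F, arma::fill::zeros);
    for (arma::uword p = 0; p < P; ++p)
      for (arma::uword b = 0; b < B; ++b)
        if ((arma::sword)(p + l) <= (arma::sword)lens(b))
          for (arma::uword f = 0; f < F; ++f) {
            double v = C(p * B + b, f);
            if (v > pool(b, f)) pool(b, f) = v;
          }
    logit += pool * headW.subvec(off, off + F - 1);
    off += F;
  }
  return 1.0 / (1.0 + arma::exp(-logit));
}
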