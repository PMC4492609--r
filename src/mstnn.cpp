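// Core numerics for leaky-integrator convolutional networks.
//
// Layout conventions (shared with the R side):
//  * a feature stack over a whole sequence is an arma::cube of dimension
//    (rows, cols, maps * T) with slice index m + maps * t — identical in
//    memory to an R array dim = c(rows, cols, maps, T);
//  * kernels arrive as R arrays dim = c(kr, kc, nin, nout); viewed
//    column-major they are an (kr*kc*nin) x nout matrix whose row index
//    p = dr + kr*(dc + kc*n) matches the im2col patch ordering below;
//  * convolution is valid, stride-1 cross-correlation (no kernel flip).
//
// The recurrent dynamics are evaluated layer-wise over the full sequence:
// within a step, layer l reads layer l-1 at the same step and its own
// state at the previous step, so each conv block's drive can be computed
// by im2col + GEMM ahead of the (cheap) leaky scan. The time axis is
// processed in chunks small enough that the patch matrix stays
// cache-resident; patches are rebuilt chunk-wise in the backward pass
// rather than stored.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TANH_SCALE = 1.7159;
static const double TANH_GAIN = 2.0 / 3.0;
static const double PROB_FLOOR = 1e-12;
static const arma::uword CHUNK_DOUBLES = 500000; // ~4 MB patch buffer

struct ConvBlock {
  int nin, nout;
  int inrows, incols;   // input (post-pool of block below) spatial dims
  int outrows, outcols; // conv output spatial dims
  int kr, kc;
  double tau;
  int pool;             // pooling window after this conv (1 = none)
  int prows, pcols;     // pooled output dims
};

static std::vector<ConvBlock> parse_blocks(const List& plan) {
  List bl = plan["blocks"];
  std::vector<ConvBlock> out(bl.size());
  for (int i = 0; i < bl.size(); ++i) {
    List b = bl[i];
    ConvBlock& cb = out[i];
    cb.nin = as<int>(b["nin"]);       cb.nout = as<int>(b["nout"]);
    cb.inrows = as<int>(b["inrows"]); cb.incols = as<int>(b["incols"]);
    cb.outrows = as<int>(b["outrows"]); cb.outcols = as<int>(b["outcols"]);
    cb.kr = as<int>(b["kr"]);         cb.kc = as<int>(b["kc"]);
    cb.tau = as<double>(b["tau"]);    cb.pool = as<int>(b["pool"]);
    cb.prows = as<int>(b["prows"]);   cb.pcols = as<int>(b["pcols"]);
  }
  return out;
}

static inline double phi(double u) { return TANH_SCALE * std::tanh(TANH_GAIN * u); }
// derivative of phi expressed through v = phi(u)
static inline double phi_prime_from_v(double v) {
  return TANH_GAIN * (TANH_SCALE - v * v / TANH_SCALE);
}

static inline int chunk_steps(const ConvBlock& cb) {
  arma::uword per_step = (arma::uword)cb.outrows * cb.outcols *
                         cb.kr * cb.kc * cb.nin;
  int c = (int)std::max((arma::uword)1, CHUNK_DOUBLES / per_step);
  return c;
}

// im2col for time steps [t0, t0+tc): fills the first npos*tc rows of Pt,
// row index pos + npos*(t - t0) with pos = r + orows*c, column index
// p = dr + kr*(dc + kc*n).
static void im2col_chunk(const arma::cube& X, int maps, int t0, int tc,
                         int kr, int kc, arma::mat& Pt) {
  const int rows = X.n_rows;
  const int orows = rows - kr + 1, ocols = X.n_cols - kc + 1;
  const int npos = orows * ocols;
  for (int n = 0; n < maps; ++n) {
    for (int dc = 0; dc < kc; ++dc) {
      for (int dr = 0; dr < kr; ++dr) {
        const int p = dr + kr * (dc + kc * n);
        double* col = Pt.colptr(p);
        for (int t = 0; t < tc; ++t) {
          const arma::mat& S = X.slice(n + maps * (t0 + t));
          for (int c = 0; c < ocols; ++c)
            std::memcpy(col + (arma::uword)npos * t + (arma::uword)orows * c,
                        S.colptr(c + dc) + dr, sizeof(double) * orows);
        }
      }
    }
  }
}

// scatter-add transpose of im2col_chunk into the input gradient dX
static void col2im_chunk(const arma::mat& dPt, arma::cube& dX, int maps,
                         int t0, int tc, int kr, int kc) {
  const int rows = dX.n_rows;
  const int orows = rows - kr + 1, ocols = dX.n_cols - kc + 1;
  const int npos = orows * ocols;
  for (int n = 0; n < maps; ++n) {
    for (int dc = 0; dc < kc; ++dc) {
      for (int dr = 0; dr < kr; ++dr) {
        const int p = dr + kr * (dc + kc * n);
        const double* col = dPt.colptr(p);
        for (int t = 0; t < tc; ++t) {
          arma::mat& S = dX.slice(n + maps * (t0 + t));
          for (int c = 0; c < ocols; ++c) {
            const double* src = col + (arma::uword)npos * t + (arma::uword)orows * c;
            double* dst = S.colptr(c + dc) + dr;
            for (int r = 0; r < orows; ++r) dst[r] += src[r];
          }
        }
      }
    }
  }
}

struct BlockTrace {
  arma::cube V;     // pre-pool activations (outrows, outcols, nout*T)
  arma::cube Vp;    // post-pool activations (prows, pcols, nout*T)
  arma::ucube amax; // argmax linear index within an (outrows x outcols) map
  bool pooled;
};

// forward through all conv blocks, filling traces
static void forward_blocks(const arma::cube& frames, int T,
                           const std::vector<ConvBlock>& blocks,
                           const List& kernels, const List& kbias,
                           std::vector<BlockTrace>& traces) {
  const arma::cube* X = &frames;
  for (size_t i = 0; i < blocks.size(); ++i) {
    const ConvBlock& cb = blocks[i];
    NumericVector kv = kernels[i];
    NumericVector bv = kbias[i];
    const int plen = cb.kr * cb.kc * cb.nin;
    const int npos = cb.outrows * cb.outcols;
    arma::mat K(const_cast<double*>(kv.begin()), plen, cb.nout, false, true);
    const arma::rowvec bias(const_cast<double*>(bv.begin()), cb.nout, false, true);

    BlockTrace& tr = traces[i];
    tr.V.set_size(cb.outrows, cb.outcols, (arma::uword)cb.nout * T);
    const double a = 1.0 - 1.0 / cb.tau, s = 1.0 / cb.tau;

    const int chunk = chunk_steps(cb);
    arma::mat Pt((arma::uword)npos * chunk, plen);
    arma::mat Dt;
    arma::cube U(cb.outrows, cb.outcols, cb.nout, arma::fill::zeros);
    for (int t0 = 0; t0 < T; t0 += chunk) {
      const int tc = std::min(chunk, T - t0);
      im2col_chunk(*X, cb.nin, t0, tc, cb.kr, cb.kc, Pt);
      Dt = Pt.head_rows((arma::uword)npos * tc) * K; // (npos*tc) x nout
      Dt.each_row() += bias;
      // leaky scan: u_t = a u_{t-1} + s drive_t, u_0 = 0; store v = phi(u)
      for (int t = 0; t < tc; ++t) {
        for (int m = 0; m < cb.nout; ++m) {
          const double* dptr = Dt.colptr(m) + (arma::uword)npos * t;
          double* uptr = U.slice_memptr(m);
          double* vptr = tr.V.slice_memptr(m + (arma::uword)cb.nout * (t0 + t));
          for (int j = 0; j < npos; ++j) {
            uptr[j] = a * uptr[j] + s * dptr[j];
            vptr[j] = phi(uptr[j]);
          }
        }
      }
    }

    // max pooling with argmax bookkeeping
    if (cb.pool > 1) {
      tr.pooled = true;
      tr.Vp.set_size(cb.prows, cb.pcols, (arma::uword)cb.nout * T);
      tr.amax.set_size(cb.prows, cb.pcols, (arma::uword)cb.nout * T);
      const int p = cb.pool;
      for (arma::uword sidx = 0; sidx < tr.V.n_slices; ++sidx) {
        const arma::mat& Vs = tr.V.slice(sidx);
        arma::mat& Ps = tr.Vp.slice(sidx);
        arma::umat& As = tr.amax.slice(sidx);
        for (int pc = 0; pc < cb.pcols; ++pc) {
          for (int pr = 0; pr < cb.prows; ++pr) {
            double best = -std::numeric_limits<double>::infinity();
            arma::uword barg = 0;
            for (int dc = 0; dc < p; ++dc) {
              for (int dr = 0; dr < p; ++dr) {
                arma::uword idx = (pr * p + dr) +
                  (arma::uword)cb.outrows * (pc * p + dc);
                if (Vs(idx) > best) { best = Vs(idx); barg = idx; }
              }
            }
            Ps(pr, pc) = best;
            As(pr, pc) = barg;
          }
        }
      }
    } else {
      tr.pooled = false;
      tr.Vp = tr.V; // copy; the top block is small
    }
    X = &traces[i].Vp;
  }
}

static void softmax_cols(const arma::mat& S, arma::mat& Y) {
  Y.set_size(S.n_rows, S.n_cols);
  for (arma::uword t = 0; t < S.n_cols; ++t) {
    arma::vec c = S.col(t) - S.col(t).max();
    arma::vec e = arma::exp(c);
    Y.col(t) = e / arma::accu(e);
  }
}

// [[Rcpp::export(name = ".mstnn_forward_cpp")]]
List mstnn_forward_cpp(NumericVector frames_r, List plan, List params,
                       bool record = false) {
  IntegerVector fd = frames_r.attr("dim");
  const int rows = fd[0], cols = fd[1], T = fd[2];
  arma::cube frames(frames_r.begin(), rows, cols, T, false, true);
  std::vector<ConvBlock> blocks = parse_blocks(plan);

  std::vector<BlockTrace> traces(blocks.size());
  forward_blocks(frames, T, blocks, params["kernels"], params["kbias"], traces);

  const BlockTrace& top = traces.back();
  const int F = top.Vp.n_rows * top.Vp.n_cols * blocks.back().nout;
  arma::mat Vflat(const_cast<double*>(top.Vp.memptr()), F, T, false, true);
  arma::mat W = as<arma::mat>(params["W"]);
  arma::vec wb = as<arma::vec>(params["wbias"]);
  arma::mat S = W * Vflat;
  S.each_col() += wb;
  arma::mat Y;
  softmax_cols(S, Y);

  List out = List::create(_["s"] = S, _["y"] = Y);
  if (record) {
    List vs(blocks.size());
    for (size_t i = 0; i < blocks.size(); ++i) {
      const ConvBlock& cb = blocks[i];
      NumericVector v(traces[i].V.memptr(),
                      traces[i].V.memptr() + traces[i].V.n_elem);
      v.attr("dim") = IntegerVector::create(cb.outrows, cb.outcols, cb.nout, T);
      vs[i] = v;
    }
    out["v"] = vs;
  }
  return out;
}

// [[Rcpp::export(name = ".mstnn_bptt_cpp")]]
List mstnn_bptt_cpp(NumericVector frames_r, List plan, List params,
                    int target, int d, bool literal_window = false) {
  IntegerVector fd = frames_r.attr("dim");
  const int rows = fd[0], cols = fd[1], T = fd[2];
  arma::cube frames(frames_r.begin(), rows, cols, T, false, true);
  std::vector<ConvBlock> blocks = parse_blocks(plan);
  const int nb = blocks.size();
  const int C = as<int>(plan["classes"]);
  List kernels = params["kernels"], kbias = params["kbias"];

  std::vector<BlockTrace> traces(nb);
  forward_blocks(frames, T, blocks, kernels, kbias, traces);

  const BlockTrace& top = traces.back();
  const int F = top.Vp.n_rows * top.Vp.n_cols * blocks.back().nout;
  arma::mat Vflat(const_cast<double*>(top.Vp.memptr()), F, T, false, true);
  arma::mat W = as<arma::mat>(params["W"]);
  arma::vec wb = as<arma::vec>(params["wbias"]);
  arma::mat S = W * Vflat;
  S.each_col() += wb;
  arma::mat Y;
  softmax_cols(S, Y);

  // delay-response KL loss against a one-hot target
  arma::vec Et(T, arma::fill::zeros);
  arma::mat dS(C, T, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    const int t1 = t + 1;
    const bool sup = literal_window ? (T - t1 <= d) : (t1 > T - d);
    if (!sup) continue;
    Et(t) = -std::log(std::max(Y(target, t), PROB_FLOOR));
    dS.col(t) = Y.col(t);
    dS(target, t) -= 1.0;
  }
  const double E = arma::accu(Et);

  arma::mat dW = dS * Vflat.t();
  arma::vec dwb = arma::sum(dS, 1);
  arma::mat dVflat = W.t() * dS; // F x T

  // gradient wrt the top block's pooled output
  arma::cube dOut(blocks[nb - 1].prows, blocks[nb - 1].pcols,
                  (arma::uword)blocks[nb - 1].nout * T);
  std::memcpy(dOut.memptr(), dVflat.memptr(), sizeof(double) * dVflat.n_elem);

  List dkernels(nb), dkbias(nb);
  for (int i = nb - 1; i >= 0; --i) {
    const ConvBlock& cb = blocks[i];
    const int npos = cb.outrows * cb.outcols;
    const int plen = cb.kr * cb.kc * cb.nin;
    BlockTrace& tr = traces[i];
    NumericVector kv = kernels[i];
    arma::mat K(const_cast<double*>(kv.begin()), plen, cb.nout, false, true);

    // unpool: route gradient to argmax positions
    arma::cube dV(cb.outrows, cb.outcols, (arma::uword)cb.nout * T,
                  arma::fill::zeros);
    if (tr.pooled) {
      for (arma::uword sidx = 0; sidx < dV.n_slices; ++sidx) {
        arma::mat& dVs = dV.slice(sidx);
        const arma::mat& dOs = dOut.slice(sidx);
        const arma::umat& As = tr.amax.slice(sidx);
        for (arma::uword j = 0; j < dOs.n_elem; ++j) dVs(As(j)) += dOs(j);
      }
    } else {
      dV = dOut;
    }

    // backward leaky scan: g_t = dV_t .* phi'(u_t) + (1 - 1/tau) g_{t+1};
    // overwrite dV in place with g
    const double a = 1.0 - 1.0 / cb.tau, sc = 1.0 / cb.tau;
    for (int m = 0; m < cb.nout; ++m) {
      double* gnext = nullptr;
      for (int t = T - 1; t >= 0; --t) {
        const double* vptr = tr.V.slice_memptr(m + (arma::uword)cb.nout * t);
        double* gptr = dV.slice_memptr(m + (arma::uword)cb.nout * t);
        if (gnext == nullptr) {
          for (int j = 0; j < npos; ++j)
            gptr[j] = gptr[j] * phi_prime_from_v(vptr[j]);
        } else {
          for (int j = 0; j < npos; ++j)
            gptr[j] = gptr[j] * phi_prime_from_v(vptr[j]) + a * gnext[j];
        }
        gnext = gptr;
      }
    }

    // chunked accumulation of kernel/bias/input gradients
    const arma::cube& Xin = (i == 0) ? frames : traces[i - 1].Vp;
    arma::cube dXin;
    if (i > 0)
      dXin.zeros(blocks[i - 1].prows, blocks[i - 1].pcols,
                 (arma::uword)blocks[i - 1].nout * T);
    const int chunk = chunk_steps(cb);
    arma::mat Pt((arma::uword)npos * chunk, plen);
    arma::mat Gc((arma::uword)npos * chunk, cb.nout);
    arma::mat dK(plen, cb.nout, arma::fill::zeros);
    arma::rowvec db(cb.nout, arma::fill::zeros);
    for (int t0 = 0; t0 < T; t0 += chunk) {
      const int tc = std::min(chunk, T - t0);
      im2col_chunk(Xin, cb.nin, t0, tc, cb.kr, cb.kc, Pt);
      for (int t = 0; t < tc; ++t)
        for (int m = 0; m < cb.nout; ++m)
          std::memcpy(Gc.colptr(m) + (arma::uword)npos * t,
                      dV.slice_memptr(m + (arma::uword)cb.nout * (t0 + t)),
                      sizeof(double) * npos);
      const arma::uword hn = (arma::uword)npos * tc;
      dK += Pt.head_rows(hn).t() * Gc.head_rows(hn);
      db += arma::sum(Gc.head_rows(hn), 0);
      if (i > 0) {
        arma::mat dPt = Gc.head_rows(hn) * K.t(); // (npos*tc) x plen
        col2im_chunk(dPt, dXin, cb.nin, t0, tc, cb.kr, cb.kc);
      }
    }
    dK *= sc;
    db *= sc;
    if (!dK.is_finite() || !db.is_finite())
      stop("non-finite gradient in convolutional block %d", i + 1);

    NumericVector dkv(dK.memptr(), dK.memptr() + dK.n_elem);
    dkv.attr("dim") = kv.attr("dim");
    dkernels[i] = dkv;
    dkbias[i] = NumericVector(db.begin(), db.end());
    if (i > 0) {
      dXin *= sc;
      dOut = std::move(dXin);
    }
  }

  // normalize by sequence length
  const double inv_T = 1.0 / T;
  for (int i = 0; i < nb; ++i) {
    NumericVector dk = dkernels[i];
    for (R_xlen_t j = 0; j < dk.size(); ++j) dk[j] *= inv_T;
    NumericVector db = dkbias[i];
    for (R_xlen_t j = 0; j < db.size(); ++j) db[j] *= inv_T;
  }
  dW *= inv_T;
  dwb *= inv_T;
  if (!dW.is_finite() || !dwb.is_finite())
    stop("non-finite gradient in the output head");

  return List::create(
    _["grads"] = List::create(_["kernels"] = dkernels, _["kbias"] = dkbias,
                              _["W"] = dW, _["wbias"] = dwb),
    _["E"] = E, _["Et"] = NumericVector(Et.begin(), Et.end()),
    _["y"] = Y);
}
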