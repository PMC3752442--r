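// Training inner loop for the dual-pathway Elman network.
//
// The layer graph is fixed: Auditory -> {iSMG, aSTG_STS}; aSTG_STS -> vATL;
// {iSMG, vATL} -> SpeechMotor; every non-input layer has a recurrent
// (copy-back) projection from its own previous-event activation. This file
// mirrors the R reference implementation (bptt_trial / train_epoch_r)
// exactly: logistic activations, cross-entropy on event-masked targets,
// backpropagation through time over the whole trial, online updates with
// multiplicative weight decay, masked weights pinned at zero, Gaussian
// output noise (drawn from R's RNG) clipped to [0, 1].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

// layer indices
enum { AUD = 0, ISMG = 1, ASTG = 2, VATL = 3, MOTOR = 4 };
// connection indices (source, target), fixed order matching the R side:
// Auditory->iSMG, iSMG->SpeechMotor, Auditory->aSTG_STS, aSTG_STS->vATL,
// vATL->SpeechMotor
static const int CSRC[5] = {AUD, ISMG, AUD, ASTG, VATL};
static const int CTGT[5] = {ISMG, MOTOR, ASTG, VATL, MOTOR};
static const int NCOMP = 4;
static const int COMP[NCOMP] = {ISMG, ASTG, VATL, MOTOR}; // topological

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + arma::exp(-z)); }

struct Trial {
  int n_events;
  mat aud_values;            // d_aud x T
  std::vector<int> aud_clamped;
  bool has_vatl_clamp;
  mat vatl_values;           // d_vatl x T (when clamped)
  std::vector<int> vatl_clamped;
  int tgt_layer;             // VATL or MOTOR
  mat tgt_values;            // d x T
  std::vector<int> tgt_active;
};

static Trial parse_trial(const List& tr) {
  Trial t;
  t.n_events = as<int>(tr["n_events"]);
  t.aud_values = as<mat>(tr["aud_values"]);
  t.aud_clamped = as<std::vector<int>>(tr["aud_clamped"]);
  t.has_vatl_clamp = as<bool>(tr["has_vatl_clamp"]);
  if (t.has_vatl_clamp) {
    t.vatl_values = as<mat>(tr["vatl_values"]);
    t.vatl_clamped = as<std::vector<int>>(tr["vatl_clamped"]);
  }
  t.tgt_layer = as<int>(tr["tgt_layer"]); // 3 = vATL, 4 = SpeechMotor
  t.tgt_values = as<mat>(tr["tgt_values"]);
  t.tgt_active = as<std::vector<int>>(tr["tgt_active"]);
  return t;
}

static inline bool clamped_at(const Trial& t, int layer, int ev) {
  if (layer == AUD) return t.aud_clamped[ev] != 0;
  if (layer == VATL && t.has_vatl_clamp) return t.vatl_clamped[ev] != 0;
  return false;
}

// [[Rcpp::export(name = ".train_epoch_cpp")]]
List train_epoch_cpp(List W_in, List Wrec_in, List b_in, List mask_in,
                     List mask_rec_in, NumericVector noise_sd,
                     List trials, IntegerVector order,
                     double lr, double decay, double momentum,
                     double max_grad_norm, double eps) {
  std::vector<mat> W(5), mask(5), Wrec(NCOMP), mask_rec(NCOMP);
  std::vector<vec> b(NCOMP);
  for (int c = 0; c < 5; ++c) {
    W[c] = as<mat>(W_in[c]);
    mask[c] = as<mat>(mask_in[c]);
  }
  for (int i = 0; i < NCOMP; ++i) {
    Wrec[i] = as<mat>(Wrec_in[i]);
    mask_rec[i] = as<mat>(mask_rec_in[i]);
    b[i] = as<vec>(b_in[i]);
  }
  // noise_sd comes ordered: iSMG, aSTG_STS, vATL, SpeechMotor
  std::vector<double> nsd(NCOMP);
  for (int i = 0; i < NCOMP; ++i) nsd[i] = noise_sd[i];

  int sizes[5];
  sizes[AUD] = W[0].n_cols;
  sizes[ISMG] = W[0].n_rows;
  sizes[ASTG] = W[2].n_rows;
  sizes[VATL] = W[3].n_rows;
  sizes[MOTOR] = W[1].n_rows;

  const double keep = 1.0 - decay;
  double total_loss = 0.0;
  int n_trials = order.size();

  // momentum velocities, zeroed at the start of each epoch
  std::vector<mat> vW(5), vWrec(NCOMP);
  std::vector<vec> vb(NCOMP);
  for (int c = 0; c < 5; ++c) vW[c] = mat(arma::size(W[c]), arma::fill::zeros);
  for (int ci = 0; ci < NCOMP; ++ci) {
    vWrec[ci] = mat(arma::size(Wrec[ci]), arma::fill::zeros);
    vb[ci] = vec(Wrec[ci].n_rows, arma::fill::zeros);
  }

  std::vector<Trial> parsed(trials.size());
  for (int i = 0; i < trials.size(); ++i) parsed[i] = parse_trial(trials[i]);

  // which connections feed / leave each computed layer
  for (int oi = 0; oi < n_trials; ++oi) {
    const Trial& tr = parsed[order[oi] - 1];
    const int T = tr.n_events;

    // forward -------------------------------------------------------------
    std::vector<mat> a(5), s(5);
    for (int l = 0; l < 5; ++l) a[l] = mat(sizes[l], T, arma::fill::zeros);
    for (int ci = 0; ci < NCOMP; ++ci)
      s[COMP[ci]] = mat(sizes[COMP[ci]], T, arma::fill::zeros);

    for (int t = 0; t < T; ++t) {
      if (tr.aud_clamped[t]) a[AUD].col(t) = tr.aud_values.col(t);
      for (int ci = 0; ci < NCOMP; ++ci) {
        int l = COMP[ci];
        if (clamped_at(tr, l, t)) {
          a[l].col(t) = tr.vatl_values.col(t);
          s[l].col(t) = tr.vatl_values.col(t);
          continue;
        }
        vec z = b[ci];
        for (int c = 0; c < 5; ++c) {
          if (CTGT[c] == l) z += W[c] * a[CSRC[c]].col(t);
        }
        if (t == 0) {
          z += Wrec[ci] * vec(sizes[l], arma::fill::value(0.5));
        } else {
          z += Wrec[ci] * a[l].col(t - 1);
        }
        vec sl = sigm(z);
        s[l].col(t) = sl;
        if (nsd[ci] > 0) {
          vec noisy = sl;
          for (int u = 0; u < sizes[l]; ++u) {
            noisy[u] += nsd[ci] * R::norm_rand();
          }
          a[l].col(t) = arma::clamp(noisy, 0.0, 1.0);
        } else {
          a[l].col(t) = sl;
        }
      }
    }

    // loss ----------------------------------------------------------------
    double loss = 0.0;
    for (int t = 0; t < T; ++t) {
      if (!tr.tgt_active[t]) continue;
      vec aa = arma::clamp(a[tr.tgt_layer].col(t), eps, 1.0 - eps);
      vec y = tr.tgt_values.col(t);
      loss -= arma::accu(y % arma::log(aa) + (1.0 - y) % arma::log(1.0 - aa));
    }
    if (!std::isfinite(loss)) {
      stop("non-finite loss on trial %d", order[oi]);
    }
    total_loss += loss;

    // backward ------------------------------------------------------------
    std::vector<mat> delta(5);
    for (int ci = 0; ci < NCOMP; ++ci)
      delta[COMP[ci]] = mat(sizes[COMP[ci]], T, arma::fill::zeros);

    for (int t = T - 1; t >= 0; --t) {
      for (int ci = NCOMP - 1; ci >= 0; --ci) { // reverse topological
        int l = COMP[ci];
        if (clamped_at(tr, l, t)) continue;
        vec dL_da(sizes[l], arma::fill::zeros);
        for (int c = 0; c < 5; ++c) {
          if (CSRC[c] == l && !clamped_at(tr, CTGT[c], t)) {
            dL_da += W[c].t() * delta[CTGT[c]].col(t);
          }
        }
        if (t < T - 1 && !clamped_at(tr, l, t + 1)) {
          dL_da += Wrec[ci].t() * delta[l].col(t + 1);
        }
        // sigmoid+CE cancellation at targeted events: delta_z = a - y,
        // bounded under output noise (the literal chain rule through the
        // clipped noisy activation explodes near the clip boundary)
        vec dz = dL_da % s[l].col(t) % (1.0 - s[l].col(t));
        if (tr.tgt_layer == l && tr.tgt_active[t]) {
          dz += a[l].col(t) - tr.tgt_values.col(t);
        }
        delta[l].col(t) = dz;
      }
    }

    // gradients + online update -------------------------------------------
    std::vector<mat> gW(5), gWrec(NCOMP);
    std::vector<vec> gb(NCOMP);
    for (int c = 0; c < 5; ++c) gW[c] = mat(arma::size(W[c]), arma::fill::zeros);
    for (int ci = 0; ci < NCOMP; ++ci) {
      gWrec[ci] = mat(arma::size(Wrec[ci]), arma::fill::zeros);
      gb[ci] = vec(sizes[COMP[ci]], arma::fill::zeros);
    }
    for (int t = 0; t < T; ++t) {
      for (int ci = 0; ci < NCOMP; ++ci) {
        int l = COMP[ci];
        if (clamped_at(tr, l, t)) continue;
        const vec& d = delta[l].col(t);
        for (int c = 0; c < 5; ++c) {
          if (CTGT[c] == l) gW[c] += d * a[CSRC[c]].col(t).t();
        }
        if (t == 0) {
          gWrec[ci] += d * arma::rowvec(sizes[l], arma::fill::value(0.5));
        } else {
          gWrec[ci] += d * a[l].col(t - 1).t();
        }
        gb[ci] += d;
      }
    }
    // global gradient-norm clipping: novel task demands (and noisy
    // forwards) can produce per-trial gradients far outside the trained
    // regime; rescaling preserves direction while bounding the step
    if (std::isfinite(max_grad_norm)) {
      double sq = 0.0;
      for (int c = 0; c < 5; ++c) sq += arma::accu(gW[c] % gW[c]);
      for (int ci = 0; ci < NCOMP; ++ci) {
        sq += arma::accu(gWrec[ci] % gWrec[ci]);
        sq += arma::dot(gb[ci], gb[ci]);
      }
      double gnorm = std::sqrt(sq);
      if (gnorm > max_grad_norm) {
        double sc = max_grad_norm / gnorm;
        for (int c = 0; c < 5; ++c) gW[c] *= sc;
        for (int ci = 0; ci < NCOMP; ++ci) {
          gWrec[ci] *= sc;
          gb[ci] *= sc;
        }
      }
    }

    // normalized momentum: the learning rate scales the exponentially
    // smoothed gradient, so the effective step stays lr as momentum varies
    const double gw_scale = 1.0 - momentum;
    for (int c = 0; c < 5; ++c) {
      vW[c] = momentum * vW[c] + gw_scale * gW[c];
      W[c] = ((W[c] - lr * vW[c]) * keep) % mask[c];
    }
    for (int ci = 0; ci < NCOMP; ++ci) {
      vWrec[ci] = momentum * vWrec[ci] + gw_scale * gWrec[ci];
      Wrec[ci] = ((Wrec[ci] - lr * vWrec[ci]) * keep) % mask_rec[ci];
      vb[ci] = momentum * vb[ci] + gw_scale * gb[ci];
      b[ci] = (b[ci] - lr * vb[ci]) * keep;
    }
  }

  List W_out(5), Wrec_out(NCOMP), b_out(NCOMP);
  for (int c = 0; c < 5; ++c) W_out[c] = W[c];
  for (int ci = 0; ci < NCOMP; ++ci) {
    Wrec_out[ci] = Wrec[ci];
    b_out[ci] = b[ci];
  }
  return List::create(_["W"] = W_out, _["Wrec"] = Wrec_out, _["b"] = b_out,
                      _["mean_loss"] = total_loss / n_trials);
}
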