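// GRU value network: forward pass and semi-gradient TD training (BPTT + Adam).
//
// Parameter layout (names must match the R side):
//   W_ir, W_iu, W_in : H x 2 input weights (reset, update, candidate)
//   W_hr, W_hu, W_hn : H x H recurrent weights
//   b_ir, b_iu, b_in, b_hr, b_hu, b_hn : H biases
//   w : H value readout, w0 : scalar offset
//
// TD pairing: delta_t = r_{t+1} + gamma * V_{t+1} - V_t on the transition
// t -> t+1; the bootstrap target (r + gamma*V_{t+1}) is treated as a
// constant under differentiation (semi-gradient).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct GruParams {
  mat Wir, Wiu, Win, Whr, Whu, Whn;
  vec bir, biu, bin, bhr, bhu, bhn, w;
  double w0;
  int H;
};

GruParams unpack(const Rcpp::List& p) {
  GruParams g;
  g.Wir = Rcpp::as<mat>(p["W_ir"]); g.Wiu = Rcpp::as<mat>(p["W_iu"]);
  g.Win = Rcpp::as<mat>(p["W_in"]); g.Whr = Rcpp::as<mat>(p["W_hr"]);
  g.Whu = Rcpp::as<mat>(p["W_hu"]); g.Whn = Rcpp::as<mat>(p["W_hn"]);
  g.bir = Rcpp::as<vec>(p["b_ir"]); g.biu = Rcpp::as<vec>(p["b_iu"]);
  g.bin = Rcpp::as<vec>(p["b_in"]); g.bhr = Rcpp::as<vec>(p["b_hr"]);
  g.bhu = Rcpp::as<vec>(p["b_hu"]); g.bhn = Rcpp::as<vec>(p["b_hn"]);
  g.w = Rcpp::as<vec>(p["w"]);
  g.w0 = Rcpp::as<double>(p["w0"]);
  g.H = g.Whr.n_rows;
  return g;
}

Rcpp::List pack(const GruParams& g) {
  return Rcpp::List::create(
      Rcpp::Named("W_ir") = g.Wir, Rcpp::Named("W_iu") = g.Wiu,
      Rcpp::Named("W_in") = g.Win, Rcpp::Named("W_hr") = g.Whr,
      Rcpp::Named("W_hu") = g.Whu, Rcpp::Named("W_hn") = g.Whn,
      Rcpp::Named("b_ir") = g.bir, Rcpp::Named("b_iu") = g.biu,
      Rcpp::Named("b_in") = g.bin, Rcpp::Named("b_hr") = g.bhr,
      Rcpp::Named("b_hu") = g.bhu, Rcpp::Named("b_hn") = g.bhn,
      Rcpp::Named("w") = g.w, Rcpp::Named("w0") = g.w0);
}

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// one batched GRU step; O is 2 x B, Zp is H x B
void gru_step_batch(const GruParams& g, const mat& O, const mat& Zp,
                    mat& R, mat& U, mat& HN, mat& N, mat& Z) {
  R = sigmoid(g.Wir * O + g.Whr * Zp +
              repmat(g.bir + g.bhr, 1, O.n_cols));
  U = sigmoid(g.Wiu * O + g.Whu * Zp +
              repmat(g.biu + g.bhu, 1, O.n_cols));
  HN = g.Whn * Zp + repmat(g.bhn, 1, O.n_cols);
  N = tanh(g.Win * O + repmat(g.bin, 1, O.n_cols) + R % HN);
  Z = (1.0 - U) % N + U % Zp;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_gru_forward(Rcpp::List params, arma::mat obs) {
  GruParams g = unpack(params);
  const int T = obs.n_rows;
  mat Z(T, g.H);
  vec V(T);
  mat z = zeros<mat>(g.H, 1);
  mat R, U, HN, N, Znew;
  for (int t = 0; t < T; ++t) {
    mat O = obs.row(t).t();
    gru_step_batch(g, O, z, R, U, HN, N, Znew);
    z = Znew;
    Z.row(t) = z.t();
    V(t) = dot(g.w, z.col(0)) + g.w0;
  }
  return Rcpp::List::create(Rcpp::Named("Z") = Z, Rcpp::Named("V") = V);
}

// [[Rcpp::export]]
Rcpp::List cpp_train_td(Rcpp::List params, arma::mat obs,
                        arma::imat episodes, double gamma, double lr,
                        int max_epochs, int batch_size, int patience,
                        bool train_phi, int seed) {
  GruParams g = unpack(params);
  const int H = g.H;
  const int n_ep = episodes.n_rows;
  if (n_ep < 1) Rcpp::stop("no episodes");

  // flatten parameters for Adam bookkeeping: 12 GRU tensors + readout
  std::vector<mat*> tensors = {&g.Wir, &g.Wiu, &g.Win, &g.Whr, &g.Whu, &g.Whn};
  std::vector<vec*> vecs = {&g.bir, &g.biu, &g.bin, &g.bhr, &g.bhu, &g.bhn,
                            &g.w};
  std::vector<mat> m_t(6), v_t(6), gmat(6);
  std::vector<vec> m_v(7), v_v(7), gvec(7);
  for (int i = 0; i < 6; ++i) {
    m_t[i] = zeros<mat>(tensors[i]->n_rows, tensors[i]->n_cols);
    v_t[i] = m_t[i];
  }
  for (int i = 0; i < 7; ++i) {
    m_v[i] = zeros<vec>(vecs[i]->n_elem);
    v_v[i] = m_v[i];
  }
  double m_w0 = 0, v_w0 = 0, g_w0 = 0;

  const double beta1 = 0.9, beta2 = 0.999, eps_adam = 1e-8;
  long adam_step = 0;

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<int> order(n_ep);
  for (int i = 0; i < n_ep; ++i) order[i] = i;

  std::vector<double> loss_hist;
  GruParams best = g;
  double best_loss = datum::inf;
  int best_epoch = 0, n_increase = 0;
  double prev_loss = datum::inf;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0.0;

    for (int b0 = 0; b0 < n_ep; b0 += batch_size) {
      const int B = std::min(batch_size, n_ep - b0);
      ivec starts(B), lens(B);
      int Tmax = 0;
      for (int j = 0; j < B; ++j) {
        const int e = order[b0 + j];
        starts(j) = episodes(e, 0) - 1;  // to 0-based
        lens(j) = episodes(e, 1) - episodes(e, 0) + 1;
        Tmax = std::max(Tmax, (int)lens(j));
      }

      cube Zs(H, B, Tmax), Rg(H, B, Tmax), Ug(H, B, Tmax),
           Nc(H, B, Tmax), HNs(H, B, Tmax);
      cube Os(2, B, Tmax, fill::zeros);
      mat V(Tmax, B, fill::zeros);

      mat z = zeros<mat>(H, B);
      mat R, U, HN, N, Znew;
      for (int t = 0; t < Tmax; ++t) {
        mat O(2, B, fill::zeros);
        for (int j = 0; j < B; ++j) {
          if (t < lens(j)) O.col(j) = obs.row(starts(j) + t).t();
        }
        Os.slice(t) = O;
        gru_step_batch(g, O, z, R, U, HN, N, Znew);
        z = Znew;
        Zs.slice(t) = z; Rg.slice(t) = R; Ug.slice(t) = U;
        Nc.slice(t) = N; HNs.slice(t) = HN;
        V.row(t) = g.w.t() * z + g.w0;
      }

      // TD errors and dL/dV (loss: mean over episodes of mean delta^2)
      mat dV(Tmax, B, fill::zeros);
      double batch_loss = 0.0;
      for (int j = 0; j < B; ++j) {
        const int L = lens(j);
        if (L < 2) continue;
        double ep_loss = 0.0;
        for (int t = 0; t + 1 < L; ++t) {
          const double r_next = obs(starts(j) + t + 1, 1);
          const double delta = r_next + gamma * V(t + 1, j) - V(t, j);
          ep_loss += delta * delta;
          dV(t, j) += -2.0 * delta / ((L - 1) * (double)B);
        }
        batch_loss += ep_loss / (L - 1);
      }
      epoch_loss += batch_loss;

      // backward pass
      for (int i = 0; i < 6; ++i) gmat[i].zeros(tensors[i]->n_rows,
                                                tensors[i]->n_cols);
      for (int i = 0; i < 7; ++i) gvec[i].zeros(vecs[i]->n_elem);
      g_w0 = 0;

      mat dZnext = zeros<mat>(H, B);
      for (int t = Tmax - 1; t >= 0; --t) {
        mat dZ = dZnext;
        dZ += g.w * dV.row(t);                 // value readout path
        gvec[6] += Zs.slice(t) * dV.row(t).t();
        g_w0 += accu(dV.row(t));

        const mat& Zp = (t == 0) ? zeros<mat>(H, B) : Zs.slice(t - 1);
        const mat& R = Rg.slice(t);
        const mat& U = Ug.slice(t);
        const mat& N = Nc.slice(t);
        const mat& HN = HNs.slice(t);
        const mat& O = Os.slice(t);

        mat du = dZ % (Zp - N);
        mat dn = dZ % (1.0 - U);
        mat dZp = dZ % U;

        mat dan = dn % (1.0 - N % N);
        mat dhn = dan % R;
        mat dr = dan % HN;
        mat dar = dr % R % (1.0 - R);
        mat dau = du % U % (1.0 - U);

        if (train_phi) {
          gmat[0] += dar * O.t(); gmat[3] += dar * Zp.t();
          gmat[1] += dau * O.t(); gmat[4] += dau * Zp.t();
          gmat[2] += dan * O.t(); gmat[5] += dhn * Zp.t();
          gvec[0] += sum(dar, 1); gvec[3] += sum(dar, 1);
          gvec[1] += sum(dau, 1); gvec[4] += sum(dau, 1);
          gvec[2] += sum(dan, 1); gvec[5] += sum(dhn, 1);
        }
        dZp += g.Whr.t() * dar + g.Whu.t() * dau + g.Whn.t() * dhn;
        dZnext = dZp;
      }

      // Adam update
      adam_step += 1;
      const double bc1 = 1.0 - std::pow(beta1, (double)adam_step);
      const double bc2 = 1.0 - std::pow(beta2, (double)adam_step);
      if (train_phi) {
        for (int i = 0; i < 6; ++i) {
          m_t[i] = beta1 * m_t[i] + (1 - beta1) * gmat[i];
          v_t[i] = beta2 * v_t[i] + (1 - beta2) * square(gmat[i]);
          *tensors[i] -= lr * (m_t[i] / bc1) / (sqrt(v_t[i] / bc2) + eps_adam);
        }
        for (int i = 0; i < 6; ++i) {
          m_v[i] = beta1 * m_v[i] + (1 - beta1) * gvec[i];
          v_v[i] = beta2 * v_v[i] + (1 - beta2) * square(gvec[i]);
          *vecs[i] -= lr * (m_v[i] / bc1) / (sqrt(v_v[i] / bc2) + eps_adam);
        }
      }
      m_v[6] = beta1 * m_v[6] + (1 - beta1) * gvec[6];
      v_v[6] = beta2 * v_v[6] + (1 - beta2) * square(gvec[6]);
      g.w -= lr * (m_v[6] / bc1) / (sqrt(v_v[6] / bc2) + eps_adam);
      m_w0 = beta1 * m_w0 + (1 - beta1) * g_w0;
      v_w0 = beta2 * v_w0 + (1 - beta2) * g_w0 * g_w0;
      g.w0 -= lr * (m_w0 / bc1) / (std::sqrt(v_w0 / bc2) + eps_adam);
    }

    epoch_loss /= n_ep;
    if (!std::isfinite(epoch_loss)) {
      Rcpp::stop("TD training diverged (non-finite loss at epoch %d)",
                 epoch + 1);
    }
    loss_hist.push_back(epoch_loss);
    if (epoch_loss < best_loss) {
      best_loss = epoch_loss;
      best = g;
      best_epoch = epoch + 1;
    }
    if (epoch_loss > prev_loss) {
      if (++n_increase >= patience) { prev_loss = epoch_loss; break; }
    } else {
      n_increase = 0;
    }
    prev_loss = epoch_loss;
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("params") = pack(best),
      Rcpp::Named("loss") = loss_hist,
      Rcpp::Named("best_epoch") = best_epoch);
}
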