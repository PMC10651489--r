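#include <Rcpp.h>
using namespace Rcpp;

// Zone of a position under the shared-variance maximum-likelihood partition.
// Equal variances make max-density equal nearest-centre; ties: other beats
// both reward wells (miss), water beats food.
// codes: 0 = water, 1 = food, 2 = miss
static inline int zone_code(double x, double y,
                            const double *mo, const double *mw,
                            const double *mf) {
  double dw = (x - mw[0]) * (x - mw[0]) + (y - mw[1]) * (y - mw[1]);
  double df = (x - mf[0]) * (x - mf[0]) + (y - mf[1]) * (y - mf[1]);
  double d_o = (x - mo[0]) * (x - mo[0]) + (y - mo[1]) * (y - mo[1]);
  if (d_o <= dw && d_o <= df) return 2;
  if (dw <= df) return 0;
  return 1;
}

// Core discretized Langevin session integrator.
//
// Positions x_0 .. x_{n_steps} are advanced by explicit Euler-Maruyama:
//   x <- x + dt * g * (-grad U) + sqrt(dt) * n * N(0, I)
// with U(x) = -log(s*T*phi_w + s*H*phi_f + phi_o). Trials are evaluated at
// their step (position *before* that step's integration); rewarded Go
// outcomes enqueue a need decrement applied delay_steps later. stim_add, if
// non-empty (length n_steps + 1), is added to the thirst magnitude used by
// the dynamics at each step. force_steps apply an instantaneous impulse
// along the goal dimension carrying the state force_margin past the saddle
// projection, used by the forced-transition alternative model.
//
// [[Rcpp::export]]
List cpp_simulate(NumericVector x0, double T0, double H0,
                  NumericVector mu_o, NumericVector mu_w, NumericVector mu_f,
                  double sigma2, double g, double n, double s,
                  double dt, int n_steps,
                  IntegerVector trial_steps, IntegerVector is_go,
                  double r_w, double r_f, int delay_steps, bool feedback,
                  NumericVector stim_add, IntegerVector force_steps,
                  double force_margin, int miss_limit, int record_stride) {
  const int n_tr = trial_steps.size();
  const double mo[2] = {mu_o[0], mu_o[1]};
  const double mw[2] = {mu_w[0], mu_w[1]};
  const double mf[2] = {mu_f[0], mu_f[1]};
  const double sq_dt = std::sqrt(dt);
  const bool has_stim = stim_add.size() > 0;

  // goal-dimension unit vector and saddle projection (midpoint of w/f)
  double ux = mw[0] - mf[0], uy = mw[1] - mf[1];
  double un = std::sqrt(ux * ux + uy * uy);
  ux /= un; uy /= un;
  const double p_mid = 0.5 * ((mw[0] + mf[0]) * ux + (mw[1] + mf[1]) * uy);

  // FIFO of pending need decrements (all share one fixed delay)
  std::vector<int> due_step; due_step.reserve(n_tr);
  std::vector<int> due_kind; due_kind.reserve(n_tr); // 0 water, 1 food
  size_t q_head = 0;

  int n_rec = n_steps / record_stride + 1;
  if (n_steps % record_stride != 0) n_rec += 1;
  NumericMatrix traj(n_rec, 2);
  IntegerVector rec_step(n_rec);

  IntegerVector out_zone(n_tr);
  NumericVector out_T(n_tr), out_H(n_tr);

  double x = x0[0], y = x0[1];
  double T = T0, H = H0;
  int tr_i = 0, rec_i = 0, miss_run = 0;
  int end_step = n_steps, trials_done = 0;
  size_t f_i = 0;

  for (int step = 0; step <= n_steps; ++step) {
    // 1) deliver due need decrements (clamped at zero)
    while (q_head < due_step.size() && due_step[q_head] <= step) {
      if (due_kind[q_head] == 0) T = std::max(0.0, T - r_w);
      else H = std::max(0.0, H - r_f);
      ++q_head;
    }
    // 2) forced-transition impulse: jump past the saddle projection
    while (f_i < (size_t)force_steps.size() && force_steps[f_i] == step) {
      double p = x * ux + y * uy;
      double target = (p >= p_mid) ? p_mid - force_margin
                                   : p_mid + force_margin;
      x += (target - p) * ux;
      y += (target - p) * uy;
      ++f_i;
    }
    // 3) trial evaluation at the pre-integration position
    while (tr_i < n_tr && trial_steps[tr_i] == step) {
      int z = zone_code(x, y, mo, mw, mf);
      out_zone[tr_i] = z;
      out_T[tr_i] = T;
      out_H[tr_i] = H;
      if (is_go[tr_i] == 1) {
        if (z == 2) {
          ++miss_run;
        } else {
          miss_run = 0;
          if (feedback) {
            due_step.push_back(step + delay_steps);
            due_kind.push_back(z);
          }
        }
      }
      ++tr_i;
      trials_done = tr_i;
      if (miss_limit > 0 && miss_run >= miss_limit) {
        end_step = step;
        break;
      }
    }
    // 4) record
    if (step % record_stride == 0 || step == n_steps || step == end_step) {
      if (rec_i < n_rec) {
        traj(rec_i, 0) = x;
        traj(rec_i, 1) = y;
        rec_step[rec_i] = step;
        ++rec_i;
      }
    }
    if (step >= end_step || step == n_steps) break;

    // 5) Euler-Maruyama update
    double T_eff = T + (has_stim ? stim_add[step] : 0.0);
    double c = 1.0 / (2.0 * M_PI * sigma2);
    double dw2 = (x - mw[0]) * (x - mw[0]) + (y - mw[1]) * (y - mw[1]);
    double df2 = (x - mf[0]) * (x - mf[0]) + (y - mf[1]) * (y - mf[1]);
    double do2 = (x - mo[0]) * (x - mo[0]) + (y - mo[1]) * (y - mo[1]);
    double pw = s * T_eff * c * std::exp(-dw2 / (2.0 * sigma2));
    double pf = s * H * c * std::exp(-df2 / (2.0 * sigma2));
    double po = c * std::exp(-do2 / (2.0 * sigma2));
    double m = pw + pf + po;
    // -grad U = grad m / m
    double gx = (pw * (mw[0] - x) + pf * (mf[0] - x) + po * (mo[0] - x)) /
                (sigma2 * m);
    double gy = (pw * (mw[1] - y) + pf * (mf[1] - y) + po * (mo[1] - y)) /
                (sigma2 * m);
    x += dt * g * gx + sq_dt * n * norm_rand();
    y += dt * g * gy + sq_dt * n * norm_rand();
  }

  int pend_w = 0, pend_f = 0;
  for (size_t k = q_head; k < due_step.size(); ++k) {
    if (due_kind[k] == 0) ++pend_w; else ++pend_f;
  }

  return List::create(
    _["zone"] = out_zone, _["T"] = out_T, _["H"] = out_H,
    _["trials_done"] = trials_done, _["end_step"] = end_step,
    _["T_final"] = T, _["H_final"] = H,
    _["pending_water"] = pend_w, _["pending_food"] = pend_f,
    _["traj"] = traj, _["rec_step"] = rec_step, _["n_rec"] = rec_i);
}
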