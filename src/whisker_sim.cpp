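// Euler-forward core of the cortex-vibrissa simulator.
//
// The cortical rate equations and the whisker drive are integrated on the
// network clock (rate constants as printed in the model definition, one
// network time unit = time_unit_scale seconds), while the stochastic
// whisking oscillator runs on the wall clock so that its frequency is set
// directly in Hz. One call advances the full state n_steps of dt_wall
// seconds each and returns subsampled traces plus the contact-event log.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// constrained whisker configuration: minimise
//   E = k1 (tp - teq)^2 + k2/2 * th^2
// on the contact manifold sin(tp) + sin(tp - th) = wall_h, with
// th = tp - asin(wall_h - sin(tp)). Golden-section search over tp.
static double contact_energy(double tp, double teq, double k1, double k2,
                             double wall_h) {
  double th = tp - std::asin(wall_h - std::sin(tp));
  double d = tp - teq;
  return k1 * d * d + 0.5 * k2 * th * th;
}

static double contact_theta_p(double teq, double k1, double k2,
                              double wall_h) {
  const double gr = 0.6180339887498949;
  double lo = std::asin(std::min(1.0, wall_h / 2.0));
  double hi = std::min(std::max(teq, lo + 1e-12), M_PI / 2.0 - 1e-9);
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = contact_energy(c, teq, k1, k2, wall_h);
  double fd = contact_energy(d, teq, k1, k2, wall_h);
  for (int it = 0; it < 90 && (b - a) > 1e-12; ++it) {
    if (fc < fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = contact_energy(c, teq, k1, k2, wall_h);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = contact_energy(d, teq, k1, k2, wall_h);
    }
  }
  return 0.5 * (a + b);
}

// solve the whisker configuration for a given base-spring equilibrium.
// Returns (theta_p, theta_h, in_contact).
static void whisker_solve_c(double teq, double k1, double k2, double wall_h,
                            bool wall_on, double &tp, double &th,
                            bool &contact) {
  if (!wall_on || 2.0 * std::sin(std::min(std::max(teq, -M_PI / 2.0),
                                          M_PI / 2.0)) <= wall_h ||
      teq <= 0.0) {
    tp = teq; th = 0.0; contact = false;
    return;
  }
  tp = contact_theta_p(teq, k1, k2, wall_h);
  th = tp - std::asin(wall_h - std::sin(tp));
  contact = true;
}

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(const arma::mat &W, int N, arma::vec x, arma::vec a,
                 double theta_eq, double u, double v,
                 int n_steps, double dt_wall, double tus,
                 double w_x_theta, double w_theta_x,
                 double adapt_decay, double adapt_gain,
                 double input_amp, double pulse_max_ms,
                 double theta_decay, double whisk_setpoint, double f_whisk, double cpg_damp,
                 double cpg_sigma, double noise_sigma,
                 double angle_scale, double k1, double k2, double wall_h,
                 bool cpg_on, bool feedback_on, bool wall_on,
                 const arma::vec &ext_input, int out_every,
                 const arma::uvec &keep_idx) {
  const int n2 = 2 * N;
  const double dt_net = dt_wall / tus;
  const double sq_net = std::sqrt(dt_net);
  const double sq_wall = std::sqrt(dt_wall);
  const double om = 2.0 * M_PI * f_whisk;
  const int n_out = n_steps / out_every;
  const int n_keep = keep_idx.n_elem;

  arma::vec pop_mean(n_out), tp_tr(n_out), th_tr(n_out), teq_tr(n_out),
      u_tr(n_out), contact_in_tr(n_out);
  arma::mat x_keep(n_out, n_keep);

  std::vector<int> c_on, c_off, c_pulse;
  bool in_contact = false;
  double contact_ms = 0.0;
  int pulse_steps_event = 0;
  long total_pulse_steps = 0;

  double tp = theta_eq, th = 0.0;
  bool contact0;
  whisker_solve_c(theta_eq, k1, k2, wall_h, wall_on, tp, th, contact0);
  in_contact = contact0;
  if (in_contact) c_on.push_back(0);

  RNGScope scope;
  arma::vec xi(n2);

  for (int t = 0; t < n_steps; ++t) {
    // contact-detection input: active while in contact, at most pulse_max_ms
    double contact_input = 0.0;
    if (in_contact && contact_ms < pulse_max_ms) {
      contact_input = input_amp;
      ++pulse_steps_event;
      ++total_pulse_steps;
    }
    double drive = ext_input[t] + contact_input;

    // cortical rates and adaptation (network clock)
    for (int i = 0; i < n2; ++i) xi[i] = R::norm_rand();
    arma::vec rec = W * x;
    double fb = feedback_on ? w_x_theta * angle_scale * tp : 0.0;
    arma::vec x_new =
        x + dt_net * (-x + rec - a - fb + drive) + noise_sigma * sq_net * xi;
    a += dt_net * (-adapt_decay * a + adapt_gain * x);
    x = x_new;

    // whisker base-spring equilibrium driven by excitatory mean and CPG
    double exc_mean = arma::mean(x.head(N));
    double set_pt = cpg_on ? whisk_setpoint : 0.0;
    theta_eq += dt_net * (-theta_decay * (theta_eq - set_pt) +
                          w_theta_x * exc_mean + (cpg_on ? u : 0.0));

    // stochastic whisking oscillator (wall clock, frequency in Hz).
    // The rotation-decay part is linear and is advanced exactly per step;
    // forward Euler is only marginally stable for a high-Q oscillator at
    // this step size.
    // the two oscillator variates are drawn every step regardless of
    // cpg_on so that runs with the same seed share one noise stream
    // across behavioural conditions (paired comparisons).
    double xu = R::norm_rand(), xv = R::norm_rand();
    if (cpg_on) {
      double dec = std::exp(-cpg_damp * dt_wall);
      double cw = std::cos(om * dt_wall), sw = std::sin(om * dt_wall);
      double un = dec * (cw * u + sw * v) + cpg_sigma * sq_wall * xu;
      double vn = dec * (-sw * u + cw * v) + cpg_sigma * sq_wall * xv;
      u = un; v = vn;
    }

    // whisker configuration and contact bookkeeping
    bool was_contact = in_contact;
    whisker_solve_c(theta_eq, k1, k2, wall_h, wall_on, tp, th, in_contact);
    if (in_contact) {
      if (!was_contact) {
        c_on.push_back(t + 1);
        contact_ms = 0.0;
        pulse_steps_event = 0;
      } else {
        contact_ms += dt_wall * 1000.0;
      }
    } else if (was_contact) {
      c_off.push_back(t + 1);
      c_pulse.push_back(pulse_steps_event);
      contact_ms = 0.0;
      pulse_steps_event = 0;
    }

    if (!x.is_finite() || !std::isfinite(theta_eq)) {
      stop("simulation diverged at step %d", t + 1);
    }

    if ((t + 1) % out_every == 0) {
      int k = (t + 1) / out_every - 1;
      pop_mean[k] = arma::mean(x);
      for (int j = 0; j < n_keep; ++j) x_keep(k, j) = x[keep_idx[j] - 1];
      tp_tr[k] = tp; th_tr[k] = th; teq_tr[k] = theta_eq;
      u_tr[k] = u; contact_in_tr[k] = contact_input;
    }
  }
  if (in_contact) {  // event still open at the end of the run
    c_off.push_back(n_steps);
    c_pulse.push_back(pulse_steps_event);
  }

  return List::create(
      _["pop_mean"] = pop_mean, _["x_keep"] = x_keep,
      _["theta_p"] = tp_tr, _["theta_h"] = th_tr, _["theta_eq"] = teq_tr,
      _["u"] = u_tr, _["contact_input"] = contact_in_tr,
      _["contact_onsets"] = wrap(c_on), _["contact_offsets"] = wrap(c_off),
      _["contact_pulse_steps"] = wrap(c_pulse),
      _["total_pulse_steps"] = (double)total_pulse_steps,
      _["state"] = List::create(_["x"] = x, _["a"] = a,
                                _["theta_eq"] = theta_eq, _["u"] = u,
                                _["v"] = v));
}

// [[Rcpp::export(name = ".whisker_solve_cpp")]]
NumericVector whisker_solve_cpp(double theta_eq, double k1, double k2,
                                double wall_h, bool wall_on) {
  double tp, th;
  bool contact;
  whisker_solve_c(theta_eq, k1, k2, wall_h, wall_on, tp, th, contact);
  return NumericVector::create(_["theta_p"] = tp, _["theta_h"] = th,
                               _["in_contact"] = contact ? 1.0 : 0.0);
}
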