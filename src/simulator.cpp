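// Two-process synthetic fly: circadian wake drive C(t) (sum of circular
// Gaussian bumps on the 24 h ZT axis) plus a sleep homeostat H in [0,1]
// that rises during wake and decays exponentially during rest.  Rest entry
// is a per-minute logistic hazard in (b0 + bH*H - bC*C); rest exit is a
// constant spontaneous rate plus stimulus-evoked arousals whose success
// probability is logistic around an immobility-dependent threshold
// theta(d), interpolated linearly in log immobility between nodes.
//
// The random-draw layout is fixed per frame (one transition uniform, three
// settle uniforms, two movement normals) so that runs with matched seeds
// stay aligned across parameter changes; event draws (stimulus response,
// startle direction, re-sleep latency) are consumed only when the event
// fires.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double mod_pos(double x, double m) {
  return x - m * std::floor(x / m);
}

static inline double circ_diff_h(double a, double b) {
  double d = mod_pos(a - b, 24.0);
  if (d > 12.0) d = 24.0 - d;
  return d;
}

static inline double logistic(double z) {
  return 1.0 / (1.0 + std::exp(-z));
}

static double theta_interp(const std::vector<double>& ld,
                           const NumericVector& g, double d_s) {
  const int m = (int)ld.size();
  if (d_s <= 0) return g[0];
  double x = std::log(d_s);
  if (x <= ld[0]) return g[0];
  if (x >= ld[m - 1]) return g[m - 1];
  int i = 1;
  while (x > ld[i]) ++i;
  double f = (x - ld[i - 1]) / (ld[i] - ld[i - 1]);
  return g[i - 1] + f * (g[i] - g[i - 1]);
}

// [[Rcpp::export]]
List sim_fly_cpp(List par, List cfg, List stim, int n_steps) {
  // parameters
  NumericVector bump_center = par["bump_center"];
  NumericVector bump_width  = par["bump_width"];
  NumericVector bump_amp    = par["bump_amp"];
  const double rho_w = par["rho_w"], rho_s = par["rho_s"];
  const double b0 = par["b0"], bH = par["bH"], bC = par["bC"];
  const double r2w = par["r2w_per_min"];
  NumericVector th_d = par["theta_d"], th_g = par["theta_g"];
  const double slope = par["response_slope"];
  const double startle_peak = par["startle_peak_mm_s"];
  const double startle_tau_s = (double)par["startle_decay_min"] * 60.0;
  const double resleep_mean_min = par["resleep_mean_min"];
  const double shade_A = par["shade_A"], shade_k = par["shade_kappa"];
  const double step_sd = par["step_sd_mm"], jitter = par["jitter_sd_mm"];
  const double H0 = par["H0"];

  const double dt = cfg["dt_s"];
  const double L = cfg["arena_length_mm"], W = cfg["arena_width_mm"];
  const double bound = cfg["zone_boundary_mm"];

  // stimulus pulses (may be empty)
  NumericVector pulse_t = stim["pulse_t_s"];
  NumericVector pulse_g = stim["pulse_g"];
  IntegerVector pulse_train = stim["pulse_train"];   // 1-based train id
  IntegerVector pulse_idx = stim["pulse_idx"];       // 1-based within train
  const int n_trains = stim["n_trains"];
  const int n_pulse = pulse_t.size();

  std::vector<double> ld(th_d.size());
  for (int i = 0; i < th_d.size(); ++i) ld[i] = std::log(th_d[i]);

  // outputs
  NumericVector xo(n_steps), yo(n_steps), Ho(n_steps);
  IntegerVector so(n_steps);
  std::vector<double> ep_start, ep_pshade, ep_H;
  std::vector<int> ep_zone;
  IntegerVector tr_resting(n_trains, NA_INTEGER);
  NumericVector tr_immob(n_trains, NA_REAL);
  IntegerVector tr_resp(n_trains, 0);
  IntegerVector tr_pulse(n_trains, NA_INTEGER);
  NumericVector tr_resp_t(n_trains, NA_REAL);
  NumericVector tr_lat(n_trains, NA_REAL);

  RNGScope scope;

  // state
  int state = 0;                       // 0 = wake, 1 = rest
  double H = H0;
  double x = L / 2.0, y = W / 2.0;
  double settle_x = x, settle_y = y;
  double rest_start = 0.0;
  bool in_latency = false;
  double resleep_at = 0.0, startle_t = 0.0, dir = 0.0;
  int pp = 0;

  const double margin = 1.0;

  for (int i = 0; i < n_steps; ++i) {
    const double time = i * dt;
    const double zt_h = mod_pos(time / 3600.0, 24.0);

    double C = 0.0;
    for (int k = 0; k < bump_center.size(); ++k) {
      double d = circ_diff_h(zt_h, bump_center[k]);
      C += bump_amp[k] * std::exp(-0.5 * d * d /
                                  (bump_width[k] * bump_width[k]));
    }

    // stimulus pulses starting at this frame
    while (pp < n_pulse && pulse_t[pp] <= time + 1e-9) {
      const int tid = pulse_train[pp] - 1;
      if (pulse_idx[pp] == 1) {             // train onset: open the trial
        tr_resting[tid] = (state == 1) ? 1 : 0;
        tr_immob[tid] = (state == 1) ? (time - rest_start) : NA_REAL;
      }
      if (state == 1 && tr_resting[tid] == 1 && tr_resp[tid] == 0) {
        const double d_imm = time - rest_start;
        const double th = theta_interp(ld, th_g, d_imm);
        double pr;
        if (!R_finite(slope)) pr = (pulse_g[pp] >= th) ? 1.0 : 0.0;
        else pr = logistic(slope * (pulse_g[pp] - th));
        if (unif_rand() < pr) {
          tr_resp[tid] = 1;
          tr_pulse[tid] = pulse_idx[pp];
          tr_resp_t[tid] = time;
          // startled flies run along the tube axis; a random heading in
          // the 6-mm-wide arena would often fail to clear the 3-mm
          // response criterion before bouncing
          dir = (unif_rand() < 0.5) ? 0.0 : M_PI;
          const double lat_min = exp_rand() * resleep_mean_min;
          tr_lat[tid] = lat_min;
          state = 0;
          in_latency = true;
          startle_t = time;
          resleep_at = time + lat_min * 60.0;
        }
      }
      ++pp;
    }

    // fixed per-frame draw layout (keeps matched seeds aligned)
    const double u_trans = unif_rand();
    const double u_zone = unif_rand();
    const double u_sx = unif_rand();
    const double u_sy = unif_rand();
    const double z1 = norm_rand();
    const double z2 = norm_rand();

    bool enter_rest = false;
    if (state == 0) {
      H += rho_w * dt / 3600.0;
      if (H > 1.0) H = 1.0;
      if (in_latency) {
        if (time >= resleep_at) enter_rest = true;
      } else {
        const double p_min = logistic(b0 + bH * H - bC * C);
        const double p_step = (p_min >= 1.0) ? 1.0 :
          1.0 - std::pow(1.0 - p_min, dt / 60.0);
        if (u_trans < p_step) enter_rest = true;
      }
    } else {
      H *= std::exp(-rho_s * dt / 3600.0);
      const double p_wake = 1.0 - std::exp(-r2w * dt / 60.0);
      if (u_trans < p_wake) { state = 0; in_latency = false; }
    }

    if (enter_rest) {
      state = 1;
      in_latency = false;
      rest_start = time;
      const double p_shade = logistic(shade_A - shade_k * H);
      const int zone = (u_zone < p_shade) ? 0 : 1;   // 0 = zone A (shade)
      if (zone == 0) settle_x = margin + u_sx * (bound - 2.0 * margin);
      else settle_x = bound + margin + u_sx * (L - bound - 2.0 * margin);
      settle_y = margin + u_sy * (W - 2.0 * margin);
      ep_start.push_back(time);
      ep_zone.push_back(zone);
      ep_pshade.push_back(p_shade);
      ep_H.push_back(H);
    }

    // movement
    if (state == 1) {
      x = settle_x + jitter * z1;
      y = settle_y + jitter * z2;
      if (x < 0) x = 0; else if (x > L) x = L;
      if (y < 0) y = 0; else if (y > W) y = W;
    } else {
      double bstep = in_latency ?
        startle_peak * std::exp(-(time - startle_t) / startle_tau_s) * dt :
        0.0;
      if (bstep > step_sd) {
        x += std::cos(dir) * bstep + 0.2 * z1;
        y += std::sin(dir) * bstep + 0.2 * z2;
      } else {
        x += step_sd * z1;
        y += step_sd * z2;
      }
      // reflect at walls, flipping the ballistic heading
      for (int r = 0; r < 4; ++r) {
        if (x < 0) { x = -x; dir = M_PI - dir; }
        else if (x > L) { x = 2.0 * L - x; dir = M_PI - dir; }
        if (y < 0) { y = -y; dir = -dir; }
        else if (y > W) { y = 2.0 * W - y; dir = -dir; }
      }
      if (x < 0) x = 0; else if (x > L) x = L;
      if (y < 0) y = 0; else if (y > W) y = W;
    }

    xo[i] = x; yo[i] = y; so[i] = state; Ho[i] = H;
  }

  return List::create(
    _["x_mm"] = xo, _["y_mm"] = yo, _["state"] = so, _["H"] = Ho,
    _["ep_start_s"] = wrap(ep_start),
    _["ep_zone"] = wrap(ep_zone),
    _["ep_p_shade"] = wrap(ep_pshade),
    _["ep_H"] = wrap(ep_H),
    _["tr_resting"] = tr_resting,
    _["tr_prior_immobility_s"] = tr_immob,
    _["tr_responded"] = tr_resp,
    _["tr_pulse"] = tr_pulse,
    _["tr_response_s"] = tr_resp_t,
    _["tr_latency_min"] = tr_lat);
}
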