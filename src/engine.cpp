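// Inner trial loop of the two-process simulator.
//
// This is a line-for-line translation of run_trial_r()/run_phase_r(); the two
// engines are held equal draw-for-draw in the test suite. Exactly two uniform
// draws are consumed per trial (decision step, reinforcer step) so that
// lesioned variants see identical random streams.

#include <Rcpp.h>
using namespace Rcpp;

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

static inline double sigm(double u, double beta, double th) {
  return 1.0 / (1.0 + std::exp(-beta * (u - th)));
}

struct Cfg {
  int T, cue_on, cue_off, tgt_on, tgt_off, rft_on, rft_off, n_units, reward_lag;
  double dt, kappa, tau, beta_m, beta_o;
  bool trace_unit_onset;
  double s_tau, s_h, s_C, s_beta, r_tau, r_h, r_C, r_beta;
  double decision_threshold, exec_input, value_gain, beta_sr, beta_er;
  int exec_extra;
  bool gate_neg_do, gate_om_neg, both_target_inputs, rew_outer_sigmoid,
       assoc_all, rw_rule, om_always;
  double beta_om, th_om, C_j, slope_min, slope_max, th_min, th_max;
  bool meta_rectified;
  bool lesion_sr, lesion_er, inhibit;
  double decay, cscale, omega_min, theta_o_min;
};

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  List tr = cfg["trial"], cr = cfg["critic"], ac = cfg["actor"],
       me = cfg["meta"], le = cfg["lesion"], ab = cfg["ablate"];
  c.T = as<int>(tr["T"]); c.cue_on = as<int>(tr["cue_onset"]);
  c.cue_off = as<int>(tr["cue_offset"]); c.tgt_on = as<int>(tr["target_onset"]);
  c.tgt_off = as<int>(tr["target_offset"]);
  c.rft_on = as<int>(tr["reinforcer_onset"]);
  c.rft_off = as<int>(tr["reinforcer_offset"]);
  c.dt = as<double>(tr["dt"]);
  c.n_units = as<int>(cr["n_units"]);
  c.kappa = as<double>(cr["kappa"]); c.tau = as<double>(cr["tau"]);
  c.beta_m = as<double>(cr["beta_m"]); c.beta_o = as<double>(cr["beta_o"]);
  c.reward_lag = as<int>(cr["reward_lag"]);
  c.trace_unit_onset = as<std::string>(cr["trace_mode"]) == "unit_onset";
  c.s_tau = as<double>(ac["s_tau"]); c.s_h = as<double>(ac["s_h"]);
  c.s_C = as<double>(ac["s_C"]); c.s_beta = as<double>(ac["s_beta"]);
  c.r_tau = as<double>(ac["r_tau"]); c.r_h = as<double>(ac["r_h"]);
  c.r_C = as<double>(ac["r_C"]); c.r_beta = as<double>(ac["r_beta"]);
  c.decision_threshold = as<double>(ac["decision_threshold"]);
  c.exec_input = as<double>(ac["exec_input"]);
  c.exec_extra = as<int>(ac["exec_extra"]);
  c.value_gain = as<double>(ac["value_gain"]);
  c.beta_sr = as<double>(ac["beta_sr"]); c.beta_er = as<double>(ac["beta_er"]);
  c.gate_neg_do = as<std::string>(ac["gate_sr"]) == "neg_delta_o";
  c.gate_om_neg = as<std::string>(ac["gate_om"]) == "neg_delta_o";
  c.assoc_all = as<std::string>(ac["assoc_window"]) == "all";
  c.rw_rule = as<std::string>(ac["er_rule"]) == "rw_outcome";
  c.om_always = as<std::string>(cr["om_coupling"]) == "always";
  c.omega_min = as<double>(ac["omega_min"]);
  c.theta_o_min = as<double>(cr["theta_o_min"]);
  c.both_target_inputs = as<bool>(ac["both_target_inputs"]);
  c.rew_outer_sigmoid = as<bool>(ac["rew_outer_sigmoid"]);
  c.beta_om = as<double>(me["beta_om"]); c.th_om = as<double>(me["th_om"]);
  c.C_j = as<double>(me["C_j"]);
  c.slope_min = as<double>(me["slope_min"]); c.slope_max = as<double>(me["slope_max"]);
  c.th_min = as<double>(me["th_min"]); c.th_max = as<double>(me["th_max"]);
  c.meta_rectified = as<bool>(me["rectified"]);
  c.lesion_sr = as<bool>(le["s_r"]); c.lesion_er = as<bool>(le["e_r"]);
  c.inhibit = !as<bool>(ab["mutual_inhibition"]);
  c.cscale = as<bool>(cr["euler_scale"]) ? c.dt / c.tau : 1.0;
  double gamma = 1.0 - c.dt / c.tau;
  double lambda = 1.0 - (1.0 - c.dt / c.kappa) / (1.0 - c.dt / c.tau);
  c.decay = lambda * gamma;
  return c;
}

// [[Rcpp::export(name = ".run_phase_cpp")]]
List run_phase_cpp(List state, IntegerVector stimuli, NumericVector p_by_stim,
                   IntegerVector correct_by_stim, bool extinction,
                   double guess_p1, List cfg) {
  Cfg c = parse_cfg(cfg);
  NumericMatrix theta_m = clone(as<NumericMatrix>(state["theta_m"]));
  NumericMatrix theta_o = clone(as<NumericMatrix>(state["theta_o"]));
  NumericMatrix omega = clone(as<NumericMatrix>(state["omega"]));
  NumericVector meta = clone(as<NumericVector>(state["meta"]));
  const int n_trials = stimuli.size();
  const int S = theta_m.ncol();

  IntegerVector rec_stim(n_trials), rec_resp(n_trials);
  LogicalVector rec_driven(n_trials), rec_correct(n_trials), rec_rewarded(n_trials);
  NumericVector rec_rew(n_trials), rec_om(n_trials), rec_vm(n_trials), rec_vo(n_trials);

  std::vector<double> traces(c.n_units * S);
  RNGScope rngscope;

  for (int i = 0; i < n_trials; ++i) {
    const int s = stimuli[i] - 1;           // 0-based stimulus
    if (s < 0 || s >= S) stop("protocol error: invalid stimulus id");
    const double p = p_by_stim[s];
    const int correct_resp = correct_by_stim[s];
    std::fill(traces.begin(), traces.end(), 0.0);
    double u1 = c.s_h, u2 = c.s_h, u3 = c.r_h, u4 = c.r_h;
    double vm_prev = 0.0, vo_prev = 0.0;
    int chosen = 0; bool driven = false, rewarded = false;
    double rew_dec = NA_REAL, om_dec = NA_REAL, vm_dec = NA_REAL, vo_dec = NA_REAL;
    const int exec_end = c.rft_off + c.exec_extra;
    double* tr_s = &traces[(size_t)s * c.n_units];

    for (int t = 1; t <= c.T; ++t) {
      const int n = t - c.cue_on;          // 0-based unit index
      const bool has_unit = n >= 0 && n < c.n_units;
      const double vm = has_unit ? clamp01(theta_m(n, s)) : 0.0;
      const double vo = has_unit ? clamp01(theta_o(n, s)) : 0.0;
      const double lam_prev =
        (rewarded && (t - c.reward_lag) >= c.rft_on && (t - c.reward_lag) < c.rft_off)
          ? 1.0 : 0.0;
      const double d_m = lam_prev +
        (c.tau / c.dt) * ((1.0 - c.dt / c.tau) * vm - vm_prev);
      const bool outcome_now =
        t >= c.rft_on + c.reward_lag && t < c.rft_off + c.reward_lag;
      const double d_o = -((c.om_always || outcome_now) ? d_m : 0.0) +
        (c.tau / c.dt) * ((1.0 - c.dt / c.tau) * vo - vo_prev);
      const double dm_pos = d_m > 0.0 ? d_m : 0.0;
      for (int k = 0; k < c.n_units; ++k) {
        theta_m(k, s) += c.beta_m * c.cscale * dm_pos * tr_s[k];
        double v = theta_o(k, s) + c.beta_o * c.cscale * d_o * tr_s[k];
        if (std::isfinite(c.theta_o_min) && v < c.theta_o_min) v = c.theta_o_min;
        theta_o(k, s) = v;
      }
      if (c.trace_unit_onset) {
        for (int k = 0; k < c.n_units; ++k) tr_s[k] *= c.decay;
        if (has_unit) tr_s[n] = 1.0;
      } else {
        if (t < c.rft_on) {
          if (has_unit) for (int k = 0; k <= n; ++k) tr_s[k] = 1.0;
        } else {
          for (int k = 0; k < c.n_units; ++k) tr_s[k] *= c.decay;
        }
      }
      const double pm = std::min(vm_prev * c.value_gain, 1.0);
      const double po = std::min(vo_prev * c.value_gain, 1.0);
      const double lm = sigm(pm, meta[0], meta[1]);   // beta_vm, th_vm
      const double lo = sigm(po, meta[2], meta[3]);   // beta_vo, th_vo
      double rew;
      if (c.rew_outer_sigmoid)
        rew = sigm(lm - (c.inhibit ? lo : 0.0), c.beta_om, c.th_om);
      else {
        rew = lm - (c.inhibit ? lo : 0.0);
        if (rew < 0.0) rew = 0.0;
      }
      const double om = sigm(lo - (c.inhibit ? rew : 0.0), c.beta_om, c.th_om);
      const double a_s1 = sigm(u1, c.s_beta, 0.0), a_s2 = sigm(u2, c.s_beta, 0.0);
      const bool in_cue = t >= c.cue_on && t < c.cue_off;
      const bool in_tgt = t >= c.tgt_on && t < c.tgt_off;
      const double I_s1 = ((s == 0 && (in_cue || in_tgt)) ||
                           (c.both_target_inputs && in_tgt)) ? 1.0 : 0.0;
      const double I_s2 = ((s == 1 && (in_cue || in_tgt)) ||
                           (c.both_target_inputs && in_tgt)) ? 1.0 : 0.0;
      double I_r1 = omega(0, 0) * a_s1 + omega(1, 0) * a_s2 +
                    omega(2, 0) * om + omega(3, 0) * rew;
      double I_r2 = omega(0, 1) * a_s1 + omega(1, 1) * a_s2 +
                    omega(2, 1) * om + omega(3, 1) * rew;
      if (chosen > 0 && t >= c.tgt_off && t < exec_end) {
        if (chosen == 1) { I_r1 += c.exec_input; I_r2 -= c.exec_input; }
        else             { I_r2 += c.exec_input; I_r1 -= c.exec_input; }
      }
      u1 = u1 + (c.dt / c.s_tau) * (-u1 + c.s_h + c.s_C * sigm(u1, c.s_beta, 0.0) + I_s1);
      u2 = u2 + (c.dt / c.s_tau) * (-u2 + c.s_h + c.s_C * sigm(u2, c.s_beta, 0.0) + I_s2);
      u3 = u3 + (c.dt / c.r_tau) * (-u3 + c.r_h + c.r_C * sigm(u3, c.r_beta, 0.0) + I_r1);
      u4 = u4 + (c.dt / c.r_tau) * (-u4 + c.r_h + c.r_C * sigm(u4, c.r_beta, 0.0) + I_r2);
      const double o_r1 = sigm(u3, c.r_beta, 0.0), o_r2 = sigm(u4, c.r_beta, 0.0);
      if (t == c.tgt_off - 1) {
        const double u_draw = unif_rand();
        if (std::max(o_r1, o_r2) >= c.decision_threshold) {
          driven = true;
          chosen = (o_r1 == o_r2) ? (u_draw < 0.5 ? 1 : 2) : (o_r1 > o_r2 ? 1 : 2);
        } else {
          driven = false;
          chosen = (u_draw < guess_p1) ? 1 : 2;
        }
        rew_dec = rew; om_dec = om; vm_dec = vm; vo_dec = vo;
      }
      if (t == c.rft_on) {
        const double u2_draw = unif_rand();
        rewarded = !extinction && chosen == correct_resp && u2_draw < p;
      }
      const double as1 = sigm(u1, c.s_beta, 0.0), as2 = sigm(u2, c.s_beta, 0.0);
      const bool outcome_step = outcome_now;
      if (c.rw_rule) {
        if (outcome_step) {
          const double lam_tr = rewarded ? 1.0 : 0.0;
          const double pre[4] = {as1, as2, om, rew};
          const double bk[4] = {c.beta_sr, c.beta_sr, c.beta_er, c.beta_er};
          const bool on[4] = {!c.lesion_sr, !c.lesion_sr, !c.lesion_er, !c.lesion_er};
          for (int k = 0; k < 4; ++k) {
            if (!on[k]) continue;
            omega(k, 0) += bk[k] * pre[k] * o_r1 * (lam_tr - omega(k, 0));
            omega(k, 1) += bk[k] * pre[k] * o_r2 * (lam_tr - omega(k, 1));
          }
        }
      } else {
        const double gate = c.gate_neg_do ? -d_o : d_m;
        const bool learn_now = c.assoc_all || outcome_step;
        if (learn_now && !c.lesion_sr) {
          omega(0, 0) += c.beta_sr * gate * as1 * o_r1;
          omega(0, 1) += c.beta_sr * gate * as1 * o_r2;
          omega(1, 0) += c.beta_sr * gate * as2 * o_r1;
          omega(1, 1) += c.beta_sr * gate * as2 * o_r2;
        }
        if (learn_now && !c.lesion_er) {
          const double g_om = c.gate_om_neg ? -d_o : d_o;
          omega(2, 0) += c.beta_er * g_om * om * o_r1;
          omega(2, 1) += c.beta_er * g_om * om * o_r2;
          omega(3, 0) += c.beta_er * gate * rew * o_r1;
          omega(3, 1) += c.beta_er * gate * rew * o_r2;
        }
        if (learn_now && std::isfinite(c.omega_min)) {
          for (int k = 0; k < 8; ++k)
            if (omega[k] < c.omega_min) omega[k] = c.omega_min;
        }
      }
      if (t == c.rft_off) {
        if (c.meta_rectified) {
          const double step_om = std::max(d_o, 0.0) / c.C_j;
          const double step_rew = std::max(-d_o, 0.0) / c.C_j;
          meta[0] = std::min(std::max(meta[0] + step_rew, c.slope_min), c.slope_max);
          meta[1] = std::min(std::max(meta[1] - step_rew, c.th_min), c.th_max);
          meta[2] = std::min(std::max(meta[2] + step_om, c.slope_min), c.slope_max);
          meta[3] = std::min(std::max(meta[3] - step_om, c.th_min), c.th_max);
        } else {
          const double step = d_o / (c.C_j * 1.0);
          meta[0] = std::min(std::max(meta[0] - step, c.slope_min), c.slope_max);
          meta[1] = std::min(std::max(meta[1] + step, c.th_min), c.th_max);
          meta[2] = std::min(std::max(meta[2] + step, c.slope_min), c.slope_max);
          meta[3] = std::min(std::max(meta[3] - step, c.th_min), c.th_max);
        }
      }
      vm_prev = vm; vo_prev = vo;
    }
    rec_stim[i] = s + 1; rec_resp[i] = chosen; rec_driven[i] = driven;
    rec_correct[i] = (chosen == correct_resp); rec_rewarded[i] = rewarded;
    rec_rew[i] = rew_dec; rec_om[i] = om_dec; rec_vm[i] = vm_dec; rec_vo[i] = vo_dec;
  }

  List new_state = List::create(
    _["theta_m"] = theta_m, _["theta_o"] = theta_o,
    _["omega"] = omega, _["meta"] = meta);
  new_state.attr("class") = "atp_state";
  DataFrame records = DataFrame::create(
    _["stimulus"] = rec_stim, _["response"] = rec_resp, _["driven"] = rec_driven,
    _["correct"] = rec_correct, _["rewarded"] = rec_rewarded,
    _["rew_dec"] = rec_rew, _["om_dec"] = rec_om,
    _["vm_dec"] = rec_vm, _["vo_dec"] = rec_vo);
  return List::create(_["state"] = new_state, _["records"] = records);
}
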