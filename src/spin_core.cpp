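#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Direction-tuned spin network: Metropolis dynamics and the embodied
// simulation loop. All randomness is drawn from R's RNG so set.seed()
// controls every simulation end to end.
// ---------------------------------------------------------------------------

static inline double wrap_pi(double a) {
  // wrap angle to (-pi, pi]; floor-based to stay off versioned libm fmod
  a -= 2.0 * M_PI * std::floor((a + M_PI) / (2.0 * M_PI));
  if (a <= -M_PI) a += 2.0 * M_PI;
  return a;
}

static inline double pair_angle(double a, double b) {
  // angular distance in [0, pi]
  return std::fabs(wrap_pi(a - b));
}

static inline double Jkernel(double theta, double nu) {
  // J(theta) = cos(pi * (theta/pi)^nu); theta in [0, pi]
  if (theta < 0.0) theta = 0.0;
  if (theta > M_PI) theta = M_PI;
  return std::cos(M_PI * std::pow(theta / M_PI, nu));
}

// [[Rcpp::export]]
NumericVector cpp_interaction(NumericVector theta, double nu) {
  int n = theta.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = Jkernel(theta[i], nu);
  return out;
}

// Pairwise coupling matrix from preferred angles; diagonal zero (no
// self-coupling: the Hamiltonian sums over ordered pairs i != j).
// [[Rcpp::export]]
NumericMatrix cpp_coupling_matrix(NumericVector ang, double nu) {
  int n = ang.size();
  NumericMatrix J(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double v = Jkernel(pair_angle(ang[i], ang[j]), nu);
      J(i, j) = v;
      J(j, i) = v;
    }
  }
  return J;
}

static void fill_coupling(const std::vector<double>& ang, double nu,
                          std::vector<double>& J, int n) {
  for (int i = 0; i < n; ++i) {
    J[i * n + i] = 0.0;
    for (int j = i + 1; j < n; ++j) {
      double v = Jkernel(pair_angle(ang[i], ang[j]), nu);
      J[i * n + j] = v;
      J[j * n + i] = v;
    }
  }
}

// One Metropolis proposal on spin `i`: flip accepted with prob
// min(1, exp(-dH/T)), dH = -(2k/N) * (sigma' - sigma) * sum_j J_ij sigma_j.
static inline void metropolis_proposal(std::vector<int>& s,
                                       const std::vector<double>& J,
                                       int n, double coef, double T) {
  int i = (int)(unif_rand() * n);
  if (i >= n) i = n - 1;
  double field = 0.0;
  const double* Ji = &J[(size_t)i * n];
  for (int j = 0; j < n; ++j) if (s[j]) field += Ji[j];
  double dsig = s[i] ? -1.0 : 1.0;
  double dH = -coef * dsig * field;
  if (dH <= 0.0 || unif_rand() < std::exp(-dH / T)) s[i] = 1 - s[i];
}

// Metropolis chain at frozen geometry. Records, every `thin` proposals,
// the two-group order parameter m = (n1 - n2)/(n1 + n2) over active spins
// (groups taken from `group`, 0-based; spins in groups >= 2 count toward
// activity only), the active fraction, and optionally the full spin state.
// [[Rcpp::export]]
List cpp_metropolis_chain(NumericMatrix Jm, IntegerVector states,
                          double k, double T, int n_steps, int thin,
                          IntegerVector group, bool record_states) {
  int n = states.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = states[i];
  std::vector<double> J(Jm.begin(), Jm.end());
  double coef = 2.0 * k / (double)n;

  int n_rec = (thin > 0) ? n_steps / thin : 0;
  NumericVector m_rec(n_rec), act_rec(n_rec);
  IntegerMatrix s_rec(record_states ? n_rec : 0, record_states ? n : 0);

  int ri = 0;
  for (int t = 1; t <= n_steps; ++t) {
    metropolis_proposal(s, J, n, coef, T);
    if (thin > 0 && t % thin == 0 && ri < n_rec) {
      int n1 = 0, n2 = 0, na = 0;
      for (int j = 0; j < n; ++j) if (s[j]) {
        ++na;
        if (group[j] == 0) ++n1; else if (group[j] == 1) ++n2;
      }
      m_rec[ri] = (n1 + n2 > 0) ? (double)(n1 - n2) / (double)(n1 + n2) : 0.0;
      act_rec[ri] = (double)na / (double)n;
      if (record_states) for (int j = 0; j < n; ++j) s_rec(ri, j) = s[j];
      ++ri;
    }
  }
  IntegerVector sout(n);
  for (int i = 0; i < n; ++i) sout[i] = s[i];
  return List::create(_["states"] = sout, _["m"] = m_rec,
                      _["activity"] = act_rec, _["state_trace"] = s_rec);
}

// Embodied simulation: refresh goal vectors from the agent's position
// (with wrapped-Gaussian directional noise sd sigma_e), run
// `steps_per_move` Metropolis proposals, move by the consensus velocity
// V = (v0/N) sum_i p_i sigma_i, advance moving targets, repeat.
// Targets may translate in lockstep along `travel_axis` at `target_speed`,
// reversing at `bounds` (coordinates along the axis).
// [[Rcpp::export]]
List cpp_simulate_trajectory(NumericMatrix targets0, IntegerVector assignment,
                             double nu, double T, double sigma_e, double v0,
                             double dt, int steps_per_move, int burn_in,
                             int max_steps, double stop_radius,
                             NumericVector start, bool moving,
                             NumericVector travel_axis, double target_speed,
                             NumericVector bounds, bool record_targets) {
  int n = assignment.size();
  int k = targets0.nrow();
  double coef = 2.0 * k / (double)n;

  std::vector<double> tx(k), ty(k);
  for (int j = 0; j < k; ++j) { tx[j] = targets0(j, 0); ty[j] = targets0(j, 1); }
  double ax = 0.0, ay = 0.0;
  if (moving) { ax = travel_axis[0]; ay = travel_axis[1]; }
  double u = 0.0;      // lockstep offset along travel axis
  int tdir = 1;        // current travel direction sign

  double px = start[0], py = start[1];

  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = (unif_rand() < 0.5) ? 1 : 0;
  std::vector<double> ang(n), J((size_t)n * n, 0.0);
  std::vector<int> gsize(k, 0);
  for (int i = 0; i < n; ++i) ++gsize[assignment[i]];

  NumericMatrix pos(max_steps + 1, 2);
  NumericMatrix gact(max_steps + 1, k);
  NumericMatrix tpos(record_targets ? max_steps + 1 : 0,
                     record_targets ? 2 * k : 0);
  IntegerVector tdir_rec(record_targets ? max_steps + 1 : 0);
  pos(0, 0) = px; pos(0, 1) = py;
  int outcome = -1;
  int n_done = 0;

  for (int t = 1; t <= max_steps; ++t) {
    // capture check at current position, smallest target index wins ties
    for (int j = 0; j < k; ++j) {
      double dx = tx[j] + (moving ? ax * u : 0.0) - px;
      double dy = ty[j] + (moving ? ay * u : 0.0) - py;
      if (std::sqrt(dx * dx + dy * dy) <= stop_radius) { outcome = j; break; }
    }
    if (outcome >= 0) break;

    // egocentric goal vectors with directional noise
    for (int i = 0; i < n; ++i) {
      int j = assignment[i];
      double dx = tx[j] + (moving ? ax * u : 0.0) - px;
      double dy = ty[j] + (moving ? ay * u : 0.0) - py;
      double b = std::atan2(dy, dx);
      if (sigma_e > 0.0) b = wrap_pi(b + norm_rand() * sigma_e);
      ang[i] = b;
    }
    fill_coupling(ang, nu, J, n);

    if (t == 1) for (int q = 0; q < burn_in; ++q)
      metropolis_proposal(s, J, n, coef, T);
    for (int q = 0; q < steps_per_move; ++q)
      metropolis_proposal(s, J, n, coef, T);

    // consensus velocity
    double vx = 0.0, vy = 0.0;
    for (int i = 0; i < n; ++i) if (s[i]) {
      vx += std::cos(ang[i]); vy += std::sin(ang[i]);
    }
    vx *= v0 / (double)n; vy *= v0 / (double)n;
    px += vx * dt; py += vy * dt;

    pos(t, 0) = px; pos(t, 1) = py;
    for (int j = 0; j < k; ++j) gact(t, j) = 0.0;
    for (int i = 0; i < n; ++i) if (s[i]) gact(t, assignment[i]) += 1.0;
    for (int j = 0; j < k; ++j) gact(t, j) /= (double)gsize[j];
    if (record_targets) {
      for (int j = 0; j < k; ++j) {
        tpos(t, 2 * j) = tx[j] + (moving ? ax * u : 0.0);
        tpos(t, 2 * j + 1) = ty[j] + (moving ? ay * u : 0.0);
      }
      tdir_rec[t] = tdir;
    }
    n_done = t;

    if (moving) {
      u += tdir * target_speed * dt;
      if (u >= bounds[1]) { u = bounds[1]; tdir = -1; }
      else if (u <= bounds[0]) { u = bounds[0]; tdir = 1; }
    }
  }

  IntegerVector sout(n);
  for (int i = 0; i < n; ++i) sout[i] = s[i];
  return List::create(_["pos"] = pos, _["n_steps"] = n_done,
                      _["outcome"] = outcome + 1, // 0 = none, R-side 1-based
                      _["group_activity"] = gact, _["states"] = sout,
                      _["target_pos"] = tpos, _["target_dir"] = tdir_rec);
}

// ---------------------------------------------------------------------------
// Zonal collective-motion model: repulsion has absolute priority; otherwise
// attraction to + alignment with neighbours inside the interaction zone.
// Informed agents blend the social vector with a goal vector weighted by
// omega, optionally adapted by mismatch feedback.
// ---------------------------------------------------------------------------

static int count_components(const std::vector<double>& x,
                            const std::vector<double>& y,
                            int n, double thr) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  auto find = [&parent](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  double thr2 = thr * thr;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      if (dx * dx + dy * dy <= thr2) {
        int a = find(i), b = find(j);
        if (a != b) parent[a] = b;
      }
    }
  int comp = 0;
  for (int i = 0; i < n; ++i) if (find(i) == i) ++comp;
  return comp;
}

// [[Rcpp::export]]
int cpp_count_components(NumericMatrix posm, double thr) {
  int n = posm.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = posm(i, 0); y[i] = posm(i, 1); }
  return count_components(x, y, n, thr);
}

// [[Rcpp::export]]
List cpp_simulate_group(NumericMatrix pos0, NumericVector heading0,
                        IntegerVector goal, NumericMatrix targets,
                        double speed, double dt, double zor, double zoa,
                        double theta_max, double sigma_h,
                        NumericVector omega0, double omega_max, double gain,
                        double c0, bool feedback, double stop_radius,
                        double split_threshold, int split_check_every,
                        int max_steps, bool record_agents) {
  int n = pos0.nrow();
  int k = targets.nrow();
  std::vector<double> x(n), y(n), h(n), om(n), hn(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1);
    h[i] = heading0[i]; om[i] = omega0[i];
  }
  NumericMatrix cen(max_steps + 1, 2);
  NumericMatrix apos(record_agents ? max_steps + 1 : 0,
                     record_agents ? 2 * n : 0);
  double cx0 = 0.0, cy0 = 0.0;
  for (int i = 0; i < n; ++i) { cx0 += x[i]; cy0 += y[i]; }
  cen(0, 0) = cx0 / n; cen(0, 1) = cy0 / n;
  if (record_agents) for (int i = 0; i < n; ++i) {
    apos(0, 2 * i) = x[i]; apos(0, 2 * i + 1) = y[i];
  }

  int outcome = -1; // R side: 0 timeout, -1 split, else target index
  bool split = false;
  int n_done = 0;
  double zor2 = zor * zor, zoa2 = zoa * zoa;
  double maxturn = theta_max * dt;

  for (int t = 1; t <= max_steps; ++t) {
    for (int i = 0; i < n; ++i) {
      double rx = 0.0, ry = 0.0;  // repulsion
      double sx = 0.0, sy = 0.0;  // attraction + alignment
      bool rep = false;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double dx = x[j] - x[i], dy = y[j] - y[i];
        double d2 = dx * dx + dy * dy;
        if (d2 < 1e-12) continue;
        if (d2 <= zor2) {
          double d = std::sqrt(d2);
          rx -= dx / d; ry -= dy / d;
          rep = true;
        } else if (d2 <= zoa2) {
          double d = std::sqrt(d2);
          sx += dx / d + std::cos(h[j]);
          sy += dy / d + std::sin(h[j]);
        }
      }
      double dx_des, dy_des;
      if (rep && (rx != 0.0 || ry != 0.0)) {
        double nr = std::sqrt(rx * rx + ry * ry);
        dx_des = rx / nr; dy_des = ry / nr;
      } else if (!rep && (sx != 0.0 || sy != 0.0)) {
        // alignment includes the agent's own heading
        sx += std::cos(h[i]); sy += std::sin(h[i]);
        double ns = std::sqrt(sx * sx + sy * sy);
        if (ns > 1e-12) { dx_des = sx / ns; dy_des = sy / ns; }
        else { dx_des = std::cos(h[i]); dy_des = std::sin(h[i]); }
      } else {
        dx_des = std::cos(h[i]); dy_des = std::sin(h[i]);
      }
      if (goal[i] >= 0 && !rep) {
        double gx = targets(goal[i], 0) - x[i];
        double gy = targets(goal[i], 1) - y[i];
        double ng = std::sqrt(gx * gx + gy * gy);
        if (ng > 1e-12) {
          double vx2 = dx_des + om[i] * gx / ng;
          double vy2 = dy_des + om[i] * gy / ng;
          double nv = std::sqrt(vx2 * vx2 + vy2 * vy2);
          if (nv > 1e-12) { dx_des = vx2 / nv; dy_des = vy2 / nv; }
        }
      }
      double a_des = std::atan2(dy_des, dx_des);
      if (sigma_h > 0.0) a_des = wrap_pi(a_des + norm_rand() * sigma_h);
      double dlt = wrap_pi(a_des - h[i]);
      if (dlt > maxturn) dlt = maxturn;
      if (dlt < -maxturn) dlt = -maxturn;
      hn[i] = wrap_pi(h[i] + dlt);
    }
    for (int i = 0; i < n; ++i) {
      h[i] = hn[i];
      x[i] += speed * dt * std::cos(h[i]);
      y[i] += speed * dt * std::sin(h[i]);
      if (feedback && goal[i] >= 0) {
        double gx = targets(goal[i], 0) - x[i];
        double gy = targets(goal[i], 1) - y[i];
        double gb = std::atan2(gy, gx);
        double cb = std::cos(h[i] - gb);
        om[i] += gain * dt * (cb - c0);
        if (om[i] < 0.0) om[i] = 0.0;
        if (om[i] > omega_max) om[i] = omega_max;
      }
    }
    double cx = 0.0, cy = 0.0;
    for (int i = 0; i < n; ++i) { cx += x[i]; cy += y[i]; }
    cx /= n; cy /= n;
    cen(t, 0) = cx; cen(t, 1) = cy;
    if (record_agents) for (int i = 0; i < n; ++i) {
      apos(t, 2 * i) = x[i]; apos(t, 2 * i + 1) = y[i];
    }
    n_done = t;

    for (int j = 0; j < k; ++j) {
      double dx = targets(j, 0) - cx, dy = targets(j, 1) - cy;
      if (std::sqrt(dx * dx + dy * dy) <= stop_radius) { outcome = j; break; }
    }
    if (outcome >= 0) break;
    if (split_check_every > 0 && t % split_check_every == 0) {
      if (count_components(x, y, n, split_threshold) > 1) {
        split = true; break;
      }
    }
  }

  NumericVector omout(n), hout(n);
  NumericMatrix pout(n, 2);
  for (int i = 0; i < n; ++i) {
    omout[i] = om[i]; hout[i] = h[i];
    pout(i, 0) = x[i]; pout(i, 1) = y[i];
  }
  return List::create(_["centroid"] = cen, _["n_steps"] = n_done,
                      _["outcome"] = split ? -1 : outcome + 1,
                      _["omega"] = omout, _["heading"] = hout,
                      _["pos"] = pout, _["agent_pos"] = apos);
}
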