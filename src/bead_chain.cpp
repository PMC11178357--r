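// Overdamped Langevin dynamics of an active bead-spring filament, with an
// optional V-shaped steric trap. Euler-Maruyama with fixed timestep; R's
// RNG supplies the thermal noise so trajectories are reproducible from
// set.seed(). Forces: stiff harmonic bonds (rest length r0), harmonic
// bending on the turning angle at each junction, a constant active force
// along the local tangent (tail-to-head), WCA repulsion from the two trap
// walls, and isotropic thermal noise.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double wrap_angle(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a < -M_PI) a += 2.0 * M_PI;
  return a;
}

// distance from point p to segment a + u*(b-a), u in [0,1]; returns the
// closest point in (cx, cy)
static inline double point_segment(double px, double py, double ax, double ay,
                                   double bx, double by, double &cx,
                                   double &cy) {
  double vx = bx - ax, vy = by - ay;
  double len2 = vx * vx + vy * vy;
  double u = len2 > 0 ? ((px - ax) * vx + (py - ay) * vy) / len2 : 0.0;
  if (u < 0) u = 0;
  if (u > 1) u = 1;
  cx = ax + u * vx;
  cy = ay + u * vy;
  double dx = px - cx, dy = py - cy;
  return std::sqrt(dx * dx + dy * dy);
}

// [[Rcpp::export]]
List bead_chain_run_cpp(NumericMatrix pos0, double k_bond, double r0,
                        double kappa_b, double F_a, double drag, double kT,
                        double dt, double t_end, int stride,
                        NumericVector trap, double sigma_wca,
                        double wca_eps, double dev_stop_frac,
                        double sustain_time, int noise_stride) {
  const int N = pos0.nrow();
  const long n_steps = (long)std::ceil(t_end / dt);
  const int n_frames = (int)(n_steps / stride) + 1;
  std::vector<double> x(N), y(N), fx(N), fy(N);
  for (int i = 0; i < N; ++i) {
    x[i] = pos0(i, 0);
    y[i] = pos0(i, 1);
  }

  const bool has_trap = trap.size() >= 4;
  double ax = 0, ay = 0, w1x = 0, w1y = 0, w2x = 0, w2y = 0;
  if (has_trap) {
    ax = trap[0];
    ay = trap[1];
    double opening = trap[2], halflen = trap[3];
    // V opens toward -x (toward the incoming filament)
    double th1 = M_PI - opening / 2.0, th2 = M_PI + opening / 2.0;
    w1x = ax + halflen * std::cos(th1);
    w1y = ay + halflen * std::sin(th1);
    w2x = ax + halflen * std::cos(th2);
    w2y = ay + halflen * std::sin(th2);
  }
  const double rc = std::pow(2.0, 1.0 / 6.0) * sigma_wca;
  // thermal noise is applied as accumulated Brownian increments every
  // noise_stride steps (noise_stride * dt is far below any physical time
  // scale of the chain)
  if (noise_stride < 1) noise_stride = 1;
  const double noise_amp = std::sqrt(2.0 * kT * (noise_stride * dt) / drag);
  const double L_chain = (N - 1) * r0;

  NumericMatrix traj_x(n_frames, N), traj_y(n_frames, N);
  NumericVector frame_t(n_frames), frame_dev(n_frames),
      frame_energy(n_frames);
  LogicalVector frame_contact(n_frames);

  double collision_time = NA_REAL;
  double buckle_time = NA_REAL;
  double sustained_since = NA_REAL;
  bool buckled = false;
  long error_step = -1;
  int frame = 0;

  std::vector<double> tx(N > 1 ? N - 1 : 1), ty(N > 1 ? N - 1 : 1),
      bl(N > 1 ? N - 1 : 1);

  for (long step = 0; step <= n_steps; ++step) {
    // bond geometry
    double max_stretch = 0.0;
    for (int i = 0; i < N - 1; ++i) {
      double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i];
      double l = std::sqrt(dx * dx + dy * dy);
      bl[i] = l;
      tx[i] = dx / l;
      ty[i] = dy / l;
      double s = std::fabs(l - r0) / r0;
      if (s > max_stretch) max_stretch = s;
    }
    if (max_stretch > 0.2) {
      error_step = step;
      if (frame == 0) { // keep at least the initial state in the record
        frame_t[0] = step * dt;
        for (int i = 0; i < N; ++i) {
          traj_x(0, i) = x[i];
          traj_y(0, i) = y[i];
        }
        frame = 1;
      }
      break;
    }

    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    double energy = 0.0;

    // bonds
    for (int i = 0; i < N - 1; ++i) {
      double fmag = k_bond * (bl[i] - r0);
      energy += 0.5 * k_bond * (bl[i] - r0) * (bl[i] - r0);
      fx[i] += fmag * tx[i];
      fy[i] += fmag * ty[i];
      fx[i + 1] -= fmag * tx[i];
      fy[i + 1] -= fmag * ty[i];
    }
    // bending: junction j couples bonds j-1 (a) and j (b)
    for (int j = 1; j < N - 1; ++j) {
      int a = j - 1, b = j;
      double dalpha =
          wrap_angle(std::atan2(ty[b], tx[b]) - std::atan2(ty[a], tx[a]));
      double m = kappa_b * dalpha;
      energy += 0.5 * kappa_b * dalpha * dalpha;
      double pax = -ty[a] / bl[a], pay = tx[a] / bl[a];
      double pbx = -ty[b] / bl[b], pby = tx[b] / bl[b];
      fx[j + 1] -= m * pbx;
      fy[j + 1] -= m * pby;
      fx[j] += m * (pbx + pax);
      fy[j] += m * (pby + pay);
      fx[j - 1] -= m * pax;
      fy[j - 1] -= m * pay;
    }
    // active force along the local tangent, tail(i=N-1) -> head(i=0)
    if (F_a != 0.0) {
      for (int i = 0; i < N; ++i) {
        double ux, uy;
        if (i == 0) {
          ux = x[0] - x[1];
          uy = y[0] - y[1];
        } else if (i == N - 1) {
          ux = x[N - 2] - x[N - 1];
          uy = y[N - 2] - y[N - 1];
        } else {
          ux = x[i - 1] - x[i + 1];
          uy = y[i - 1] - y[i + 1];
        }
        double l = std::sqrt(ux * ux + uy * uy);
        fx[i] += F_a * ux / l;
        fy[i] += F_a * uy / l;
      }
    }
    // WCA walls
    bool contact_now = false;
    if (has_trap) {
      for (int i = 0; i < N; ++i) {
        for (int w = 0; w < 2; ++w) {
          double cx_, cy_;
          double d = w == 0 ? point_segment(x[i], y[i], ax, ay, w1x, w1y,
                                            cx_, cy_)
                            : point_segment(x[i], y[i], ax, ay, w2x, w2y,
                                            cx_, cy_);
          if (d < rc && d > 1e-12) {
            double sr2 = (sigma_wca / d) * (sigma_wca / d);
            double sr6 = sr2 * sr2 * sr2;
            double fmag = 24.0 * wca_eps * (2.0 * sr6 * sr6 - sr6) / d;
            energy += 4.0 * wca_eps * (sr6 * sr6 - sr6) + wca_eps;
            fx[i] += fmag * (x[i] - cx_) / d;
            fy[i] += fmag * (y[i] - cy_) / d;
            if (i == 0) contact_now = true;
          }
        }
      }
    }

    double t_now = step * dt;
    if (contact_now && !R_finite(collision_time)) collision_time = t_now;

    // transverse deviation of the chain from the head-tail chord
    double dev = 0.0;
    {
      double cx = x[N - 1] - x[0], cy = y[N - 1] - y[0];
      double cl = std::sqrt(cx * cx + cy * cy);
      if (cl > 1e-12) {
        for (int i = 1; i < N - 1; ++i) {
          double d = std::fabs((x[i] - x[0]) * cy - (y[i] - y[0]) * cx) / cl;
          if (d > dev) dev = d;
        }
      }
    }
    if (R_finite(collision_time) && dev_stop_frac > 0) {
      if (dev > dev_stop_frac * L_chain) {
        if (!R_finite(sustained_since)) sustained_since = t_now;
        if (t_now - sustained_since >= sustain_time) {
          buckled = true;
          buckle_time = t_now;
        }
      } else {
        sustained_since = NA_REAL;
      }
    }

    if (step % stride == 0 && frame < n_frames) {
      frame_t[frame] = t_now;
      frame_dev[frame] = dev;
      frame_energy[frame] = energy;
      frame_contact[frame] = contact_now;
      for (int i = 0; i < N; ++i) {
        traj_x(frame, i) = x[i];
        traj_y(frame, i) = y[i];
      }
      ++frame;
    }
    if (buckled) break;
    if (step == n_steps) break;

    // Euler-Maruyama update
    for (int i = 0; i < N; ++i) {
      x[i] += dt * fx[i] / drag;
      y[i] += dt * fy[i] / drag;
    }
    if (kT > 0 && step % noise_stride == 0) {
      for (int i = 0; i < N; ++i) {
        x[i] += noise_amp * norm_rand();
        y[i] += noise_amp * norm_rand();
      }
    }
  }

  return List::create(
      _["t"] = frame_t[Range(0, frame - 1)],
      _["x"] = traj_x(Range(0, frame - 1), _),
      _["y"] = traj_y(Range(0, frame - 1), _),
      _["deviation"] = frame_dev[Range(0, frame - 1)],
      _["energy"] = frame_energy[Range(0, frame - 1)],
      _["head_contact"] = frame_contact[Range(0, frame - 1)],
      _["collision_time"] = collision_time,
      _["buckled"] = buckled, _["buckle_time"] = buckle_time,
      _["error_step"] = (double)error_step);
}
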