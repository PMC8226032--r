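// Fast simulation core for embodied CTRNN agents.
//
// Semantics must match the R reference engine (run_trial(engine = "r")):
// per step, all agents (1) read sensor intensities from the previous
// world snapshot, (2) pass them through the sensor sigmoid, (3) take one
// Euler CTRNN step, (4) compute actuator outputs, (5) move synchronously
// and update emitter strengths. The R engine is the readable definition;
// this file exists because the genetic algorithm evaluates tens of
// thousands of 2000-step trials per run.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

inline double wrap2pi(double phi) {
  const double twopi = 2.0 * M_PI;
  return phi - twopi * std::floor(phi / twopi);
}

struct AgentCpp {
  int n;
  std::vector<double> wrec;   // n x n, column-major, wrec[j + n*i]: j -> i
  std::vector<double> wsens;  // 2 x n, column-major, wsens[k + 2*i]
  std::vector<double> wact;   // n x 3, column-major, wact[i + n*k]
  std::vector<double> tau, theta, gain;
  double sg, sb, ab;
  // state
  std::vector<double> y, out;
  double x, py, phi, emit;
};

void fill_agent(AgentCpp &ag, const List &par, const NumericVector &p0) {
  ag.n = as<int>(par["n_neurons"]);
  NumericMatrix wr = par["w_rec"], ws = par["w_sens"], wa = par["w_act"];
  ag.wrec.assign(wr.begin(), wr.end());
  ag.wsens.assign(ws.begin(), ws.end());
  ag.wact.assign(wa.begin(), wa.end());
  NumericVector tau = par["tau"], theta = par["theta"], gain = par["gain"];
  ag.tau.assign(tau.begin(), tau.end());
  ag.theta.assign(theta.begin(), theta.end());
  ag.gain.assign(gain.begin(), gain.end());
  ag.sg = as<double>(par["sensor_gain"]);
  ag.sb = as<double>(par["sensor_bias"]);
  ag.ab = as<double>(par["actuator_bias"]);
  ag.y.assign(ag.n, 0.0);
  ag.out.resize(ag.n);
  for (int i = 0; i < ag.n; ++i)
    ag.out[i] = sigmoid(ag.gain[i] * (ag.y[i] + ag.theta[i]));
  ag.x = p0[0];
  ag.py = p0[1];
  ag.phi = wrap2pi(p0[2]);
  // initial emitter strength: emitter actuator output at the initial state
  double e = ag.ab;
  for (int i = 0; i < ag.n; ++i) e += ag.wact[i + ag.n * 2] * ag.out[i];
  ag.emit = sigmoid(e);
}

} // namespace

// [[Rcpp::export(name = ".sim_trial_cpp")]]
List sim_trial_cpp(List agents, NumericMatrix poses0, int n_steps,
                   double dt, double radius, NumericVector sensor_angles,
                   int atten_inverse_square, int shadow_hard,
                   double occlusion, double min_distance,
                   bool sense_input) {
  const int na = agents.size();
  std::vector<AgentCpp> ag(na);
  for (int a = 0; a < na; ++a)
    fill_agent(ag[a], agents[a], poses0(a, _));

  // per-agent recorders
  std::vector<NumericMatrix> recPose, recSens, recY, recOut, recAct;
  for (int a = 0; a < na; ++a) {
    recPose.push_back(NumericMatrix(n_steps, 3));
    recSens.push_back(NumericMatrix(n_steps, 2));
    recY.push_back(NumericMatrix(n_steps, ag[a].n));
    recOut.push_back(NumericMatrix(n_steps, ag[a].n));
    recAct.push_back(NumericMatrix(n_steps, 3));
  }

  std::vector<double> sig;
  for (int step = 0; step < n_steps; ++step) {
    // snapshot of the previous world state
    double ox[2], oy[2], ophi[2], oemit[2];
    for (int a = 0; a < na; ++a) {
      ox[a] = ag[a].x; oy[a] = ag[a].py;
      ophi[a] = ag[a].phi; oemit[a] = ag[a].emit;
    }
    for (int a = 0; a < na; ++a) {
      AgentCpp &A = ag[a];
      // (1) sensor intensities from the partner's emitter
      double I[2] = {0.0, 0.0};
      if (sense_input && na == 2) {
        const int b = 1 - a;
        for (int k = 0; k < 2; ++k) {
          const double angk = ophi[a] + sensor_angles[k];
          const double sx = ox[a] + radius * std::cos(angk);
          const double sy = oy[a] + radius * std::sin(angk);
          const double dx = ox[b] - sx, dy = oy[b] - sy;
          const double d = std::sqrt(dx * dx + dy * dy);
          if (d == 0.0) continue;
          const double dc = d < min_distance ? min_distance : d;
          const double D = atten_inverse_square ? 1.0 / (dc * dc) : 1.0 / dc;
          const double cospsi =
              (std::cos(angk) * dx + std::sin(angk) * dy) / d;
          const double S = shadow_hard ? (cospsi >= 0.0 ? 1.0 : occlusion)
                                       : (1.0 + cospsi) / 2.0;
          I[k] = oemit[b] * D * S;
        }
      }
      // (2) sensor layer
      double s[2];
      for (int k = 0; k < 2; ++k) s[k] = sigmoid(A.sg * I[k] + A.sb);
      // (3) Euler CTRNN step
      const int n = A.n;
      sig.resize(n);
      for (int j = 0; j < n; ++j)
        sig[j] = sigmoid(A.gain[j] * (A.y[j] + A.theta[j]));
      std::vector<double> ynew(n);
      for (int i = 0; i < n; ++i) {
        double drive = 0.0;
        for (int j = 0; j < n; ++j) drive += A.wrec[j + n * i] * sig[j];
        for (int k = 0; k < 2; ++k) drive += A.wsens[k + 2 * i] * s[k];
        ynew[i] = A.y[i] + dt / A.tau[i] * (-A.y[i] + drive);
      }
      for (int i = 0; i < n; ++i) {
        A.y[i] = ynew[i];
        A.out[i] = sigmoid(A.gain[i] * (A.y[i] + A.theta[i]));
      }
      // (4) actuator layer
      double act[3];
      for (int k = 0; k < 3; ++k) {
        double z = A.ab;
        for (int i = 0; i < n; ++i) z += A.wact[i + n * k] * A.out[i];
        act[k] = sigmoid(z);
      }
      // (5) move (translation with the pre-step heading), update emitter
      const double v = (act[0] + act[1]) / 2.0;
      const double om = (act[1] - act[0]) / radius;
      A.x = ox[a] + v * std::cos(ophi[a]) * dt;
      A.py = oy[a] + v * std::sin(ophi[a]) * dt;
      A.phi = wrap2pi(ophi[a] + om * dt);
      A.emit = act[2];
      // record post-step state
      recPose[a](step, 0) = A.x;
      recPose[a](step, 1) = A.py;
      recPose[a](step, 2) = A.phi;
      recSens[a](step, 0) = I[0];
      recSens[a](step, 1) = I[1];
      for (int i = 0; i < n; ++i) {
        recY[a](step, i) = A.y[i];
        recOut[a](step, i) = A.out[i];
      }
      for (int k = 0; k < 3; ++k) recAct[a](step, k) = act[k];
    }
    for (int a = 0; a < na; ++a)
      for (int i = 0; i < ag[a].n; ++i)
        if (!std::isfinite(ag[a].y[i]))
          stop("simulation diverged at step %d", step + 1);
  }

  List res(na);
  for (int a = 0; a < na; ++a)
    res[a] = List::create(_["pose"] = recPose[a], _["sensors"] = recSens[a],
                          _["y"] = recY[a], _["out"] = recOut[a],
                          _["act"] = recAct[a]);
  return res;
}
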