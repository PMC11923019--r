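#include "hh.h"
using namespace Rcpp;

// N electrotonically coupled noisy neurons (gap-junction-like diffusive
// voltage coupling, (1/N) sum_j alpha_ij (V_j - V_i)) under a shared control
// input applied identically to every voltage equation. Event-based control:
// an upward crossing of the population mean voltage through `threshold`
// triggers one replay of the fixed 7 ms waveform; crossings during an active
// window are ignored; the controller re-arms as soon as the window ends.
// Per-neuron i.i.d. noise streams split deterministically from master_seed.
// [[Rcpp::export]]
List cpp_simulate_population(NumericVector V0, NumericVector n0,
                             NumericVector par, NumericMatrix alpha,
                             double T, double dt, double D,
                             double master_seed,
                             NumericVector waveform, double threshold,
                             int record_every, bool record_traces,
                             double spike_threshold, double refractory) {
  HHParams p = as_hh_params(par);
  int N = V0.size();
  if (alpha.nrow() != N || alpha.ncol() != N)
    stop("coupling matrix does not match the number of neurons");
  long nsteps = (long)std::llround(T / dt);
  int wlen = waveform.size();

  std::vector<NormalStream> rng;
  rng.reserve(N);
  for (int i = 0; i < N; ++i)
    rng.emplace_back((std::uint64_t)master_seed, (std::uint64_t)i);

  std::vector<double> V(V0.begin(), V0.end()), n(n0.begin(), n0.end());
  std::vector<double> rowsum(N, 0.0), cpl(N), cplp(N),
      F1V(N), F1n(N), Vp(N), np(N), g(N, 0.0), last_spike(N, -1e9);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) rowsum[i] += alpha(i, j);

  long nrec = nsteps / record_every + 1;
  NumericVector rt(nrec), rVbar(nrec), ru(nrec), re(nrec);
  NumericMatrix trV = record_traces ? NumericMatrix(nrec, N) : NumericMatrix(0, 0);
  NumericMatrix trn = record_traces ? NumericMatrix(nrec, N) : NumericMatrix(0, 0);
  std::vector<double> ev_times, sp_t;
  std::vector<int> sp_id;

  const double namp = std::sqrt(2.0 * D * dt);
  bool active = false;
  int kw = 0;
  double energy = 0.0;
  double Vbar_prev = 0.0;
  for (int i = 0; i < N; ++i) Vbar_prev += V[i];
  Vbar_prev /= N;

  rt[0] = 0.0; rVbar[0] = Vbar_prev; ru[0] = 0.0; re[0] = 0.0;
  if (record_traces)
    for (int i = 0; i < N; ++i) { trV(0, i) = V[i]; trn(0, i) = n[i]; }
  long ir = 1;

  for (long k = 0; k < nsteps; ++k) {
    double t = k * dt;
    double Vbar = 0.0;
    for (int i = 0; i < N; ++i) Vbar += V[i];
    Vbar /= N;

    double u = 0.0;
    if (wlen > 0) {
      if (!active && k > 0 && Vbar_prev < threshold && Vbar >= threshold) {
        active = true; kw = 0;
        ev_times.push_back(t);
      }
      if (active) u = waveform[kw];
    }

    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      const double* ac = &alpha(0, i);  // symmetric: column i == row i
      for (int j = 0; j < N; ++j) s += ac[j] * V[j];
      cpl[i] = (s - V[i] * rowsum[i]) / N;
    }
    if (D > 0.0)
      for (int i = 0; i < N; ++i) g[i] = namp * rng[i].normal();
    for (int i = 0; i < N; ++i) {
      F1V[i] = hh_fV_fast(V[i], n[i], p) + cpl[i] + u;
      F1n[i] = hh_fn_fast(V[i], n[i]);
      Vp[i] = V[i] + dt * F1V[i] + g[i];
      np[i] = n[i] + dt * F1n[i];
    }
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      const double* ac = &alpha(0, i);
      for (int j = 0; j < N; ++j) s += ac[j] * Vp[j];
      cplp[i] = (s - Vp[i] * rowsum[i]) / N;
    }
    for (int i = 0; i < N; ++i) {
      double F2V = hh_fV_fast(Vp[i], np[i], p) + cplp[i] + u;
      double F2n = hh_fn_fast(Vp[i], np[i]);
      double Vnew = V[i] + 0.5 * dt * (F1V[i] + F2V) + g[i];
      double nnew = n[i] + 0.5 * dt * (F1n[i] + F2n);
      if (!std::isfinite(Vnew) || !std::isfinite(nnew))
        stop("neuron %d blew up at t = %f ms", i + 1, t + dt);
      if (V[i] < spike_threshold && Vnew >= spike_threshold &&
          (t + dt) - last_spike[i] > refractory) {
        last_spike[i] = t + dt;
        sp_id.push_back(i + 1);
        sp_t.push_back(t + dt);
      }
      V[i] = Vnew; n[i] = nnew;
    }
    energy += u * u * dt;
    if (active) {
      ++kw;
      if (kw >= wlen) { active = false; kw = 0; }
    }
    Vbar_prev = Vbar;

    if ((k + 1) % record_every == 0) {
      double vb = 0.0;
      for (int i = 0; i < N; ++i) vb += V[i];
      rt[ir] = (k + 1) * dt; rVbar[ir] = vb / N; ru[ir] = u; re[ir] = energy;
      if (record_traces)
        for (int i = 0; i < N; ++i) { trV(ir, i) = V[i]; trn(ir, i) = n[i]; }
      ++ir;
    }
  }

  List out = List::create(
      _["t"] = rt, _["V_bar"] = rVbar, _["u"] = ru, _["cum_energy"] = re,
      _["energy"] = energy,
      _["event_times"] = NumericVector(ev_times.begin(), ev_times.end()),
      _["spike_neuron"] = IntegerVector(sp_id.begin(), sp_id.end()),
      _["spike_time"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["V_end"] = NumericVector(V.begin(), V.end()),
      _["n_end"] = NumericVector(n.begin(), n.end()));
  if (record_traces) { out["V_traces"] = trV; out["n_traces"] = trn; }
  return out;
}
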