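#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Monte Carlo core: simulate n_cycles independent cell cycles on one
// chromosome territory of B bins.
//
// Per S step:
//   1. every engaged bubble advances each unblocked fork edge by one bin;
//      an edge meeting replicated territory or a chromosome end blocks;
//      a bubble with both edges blocked dissolves, returning its factor.
//   2. each factor that was free at the start of the step makes one
//      initiation attempt: select one unreplicated competent bin
//      (IPLS > 0) uniformly at random and engage there with probability
//      IPLS(bin); engagement replicates the bin immediately.
// Snapshots of replication progress are taken on a fixed absolute-time
// cadence; the geometric G-phase wait randomizes the cadence phase
// relative to S entry, emulating an asynchronous population.
//
// RNG: R's generator, reseeded per cycle from cycle_seeds so populations
// are reproducible and order-independent.

// [[Rcpp::export(name = ".run_cycles_cpp")]]
List run_cycles_cpp(NumericVector ipls, int n_factors, int n_cycles,
                    int snapshot_period, double g_to_s_prob, int max_steps,
                    IntegerVector cycle_seeds, bool diagnostics) {
  const int B = ipls.size();
  if (B < 1) stop("empty territory");
  if (n_factors < 1) stop("n_factors must be >= 1");
  if (cycle_seeds.size() != n_cycles) stop("need one seed per cycle");

  // competent bins (positive initiation probability)
  std::vector<int> pool0;
  pool0.reserve(B);
  for (int b = 0; b < B; ++b) {
    if (ipls[b] < 0 || ipls[b] > 1) stop("IPLS values must lie in [0, 1]");
    if (ipls[b] > 0) pool0.push_back(b);
  }
  if (pool0.empty()) stop("empty landscape: IPLS has no positive values");

  IntegerVector s_length(n_cycles);
  LogicalVector completed(n_cycles);
  IntegerMatrix rep_step(B, n_cycles);
  std::fill(rep_step.begin(), rep_step.end(), NA_INTEGER);

  std::vector<int> snap_cycle, snap_step, snap_count;
  std::vector<int> init_cycle, init_step, init_bin;
  std::vector<int> dg_cycle, dg_step, dg_free, dg_bubbles, dg_new;

  NumericVector irate_sum(max_steps);
  IntegerVector irate_n(max_steps);

  Function set_seed("set.seed");

  std::vector<char> repl(B);
  std::vector<int> pool(B), pos(B);
  std::vector<int> bl(n_factors), br(n_factors);
  std::vector<char> blb(n_factors), brb(n_factors), active(n_factors);

  for (int c = 0; c < n_cycles; ++c) {
    set_seed(cycle_seeds[c]);
    GetRNGstate();

    std::fill(repl.begin(), repl.end(), 0);
    std::fill(pos.begin(), pos.end(), -1);
    int psize = (int)pool0.size();
    for (int i = 0; i < psize; ++i) {
      pool[i] = pool0[i];
      pos[pool0[i]] = i;
    }
    std::fill(active.begin(), active.end(), 0);
    int free_f = n_factors, n_bub = 0, repl_count = 0, s_step = 0;

    // G-phase wait (geometric) fixes the snapshot cadence phase
    double gw = R::rgeom(g_to_s_prob);
    int offset = (int)(((long long)gw) % snapshot_period);
    if (offset < 0) offset = 0;

    while (repl_count < B && s_step < max_steps) {
      ++s_step;
      int new_repl = 0, n_init = 0;
      int unrepl_before = B - repl_count;

      // 1. advance engaged bubbles
      for (int f = 0; f < n_factors; ++f) {
        if (!active[f]) continue;
        if (!blb[f]) {
          int nb = bl[f] - 1;
          if (nb < 0 || repl[nb]) {
            blb[f] = 1;
          } else {
            repl[nb] = 1;
            rep_step(nb, c) = s_step;
            if (pos[nb] >= 0) {
              int k = pos[nb], last = pool[psize - 1];
              pool[k] = last; pos[last] = k; pos[nb] = -1; --psize;
            }
            bl[f] = nb; ++repl_count; ++new_repl;
          }
        }
        if (!brb[f]) {
          int nb = br[f] + 1;
          if (nb >= B || repl[nb]) {
            brb[f] = 1;
          } else {
            repl[nb] = 1;
            rep_step(nb, c) = s_step;
            if (pos[nb] >= 0) {
              int k = pos[nb], last = pool[psize - 1];
              pool[k] = last; pos[last] = k; pos[nb] = -1; --psize;
            }
            br[f] = nb; ++repl_count; ++new_repl;
          }
        }
        if (blb[f] && brb[f]) {
          active[f] = 0; --n_bub; ++free_f;
        }
      }

      // 2. initiation attempts by factors free at the start of the step
      int attempts = free_f;
      for (int a = 0; a < attempts && psize > 0; ++a) {
        int k = (int)(unif_rand() * psize);
        if (k >= psize) k = psize - 1;
        int bin = pool[k];
        if (unif_rand() < ipls[bin]) {
          int slot = -1;
          for (int f = 0; f < n_factors; ++f) {
            if (!active[f]) { slot = f; break; }
          }
          active[slot] = 1;
          bl[slot] = br[slot] = bin;
          blb[slot] = brb[slot] = 0;
          repl[bin] = 1;
          rep_step(bin, c) = s_step;
          int last = pool[psize - 1];
          pool[k] = last; pos[last] = k; pos[bin] = -1; --psize;
          ++repl_count; ++new_repl; ++n_init;
          --free_f; ++n_bub;
          init_cycle.push_back(c + 1);
          init_step.push_back(s_step);
          init_bin.push_back(bin + 1);
        }
      }

      irate_sum[s_step - 1] += (double)n_init / (double)unrepl_before;
      irate_n[s_step - 1] += 1;

      if ((offset + s_step) % snapshot_period == 0 && repl_count > 0) {
        snap_cycle.push_back(c + 1);
        snap_step.push_back(s_step);
        snap_count.push_back(repl_count);
      }
      if (diagnostics) {
        dg_cycle.push_back(c + 1);
        dg_step.push_back(s_step);
        dg_free.push_back(free_f);
        dg_bubbles.push_back(n_bub);
        dg_new.push_back(new_repl);
      }
    }
    PutRNGstate();
    s_length[c] = s_step;
    completed[c] = (repl_count == B);
  }

  List out = List::create(
      _["s_length"] = s_length, _["completed"] = completed,
      _["rep_step"] = rep_step, _["snap_cycle"] = wrap(snap_cycle),
      _["snap_step"] = wrap(snap_step), _["snap_count"] = wrap(snap_count),
      _["init_cycle"] = wrap(init_cycle), _["init_step"] = wrap(init_step),
      _["init_bin"] = wrap(init_bin), _["irate_sum"] = irate_sum,
      _["irate_n"] = irate_n);
  if (diagnostics) {
    out["diag"] = DataFrame::create(
        _["cycle"] = wrap(dg_cycle), _["step"] = wrap(dg_step),
        _["free_factors"] = wrap(dg_free), _["bubbles"] = wrap(dg_bubbles),
        _["new_replicated"] = wrap(dg_new));
  }
  return out;
}

// Gate-count accumulation: for every snapshot of a complete cycle, assign
// the snapshot to a DNA-content gate by its replicated fraction (half-open
// intervals (b[g-1], b[g]]), then increment, for every bin already
// replicated at that snapshot, the bin's count in that gate.

// [[Rcpp::export(name = ".count_by_gate_cpp")]]
IntegerMatrix count_by_gate_cpp(IntegerMatrix rep_step, IntegerVector snap_cycle,
                                IntegerVector snap_step, IntegerVector snap_count,
                                LogicalVector completed, NumericVector boundaries) {
  const int B = rep_step.nrow();
  const int G = boundaries.size() + 1;
  const int S = snap_cycle.size();
  IntegerMatrix counts(B, G);
  for (int s = 0; s < S; ++s) {
    int c = snap_cycle[s] - 1;
    if (!completed[c]) continue;
    double f = (double)snap_count[s] / (double)B;
    int g = 0;
    while (g < G - 1 && f > boundaries[g]) ++g;
    int st = snap_step[s];
    for (int b = 0; b < B; ++b) {
      int t = rep_step(b, c);
      if (t != NA_INTEGER && t <= st) counts(b, g) += 1;
    }
  }
  return counts;
}

// Replicated-count histogram: H[b, j] = number of snapshots (complete
// cycles only) in which bin b was replicated while the cell had exactly j
// replicated bins. Sufficient statistic for gate counts under any gate
// boundaries; lets the annealer re-gate in O(B * G) per proposal.

// [[Rcpp::export(name = ".count_hist_cpp")]]
IntegerMatrix count_hist_cpp(IntegerMatrix rep_step, IntegerVector snap_cycle,
                             IntegerVector snap_step, IntegerVector snap_count,
                             LogicalVector completed) {
  const int B = rep_step.nrow();
  const int S = snap_cycle.size();
  IntegerMatrix H(B, B);
  for (int s = 0; s < S; ++s) {
    int c = snap_cycle[s] - 1;
    if (!completed[c]) continue;
    int j = snap_count[s] - 1;
    int st = snap_step[s];
    for (int b = 0; b < B; ++b) {
      int t = rep_step(b, c);
      if (t != NA_INTEGER && t <= st) H(b, j) += 1;
    }
  }
  return H;
}
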