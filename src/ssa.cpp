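// Exact continuous-time SSA for the multitype branching process on a graph,
// tracking vertex lineages.  The population is partitioned into lineage
// classes (cells sharing the same vertex-lineage); each class contributes
// count * (alpha + beta + sum of outgoing nu) to the total event rate.
// Division adds one cell to the class, death removes one, and a transition
// (x) -> (x),(y) leaves the source class untouched while adding one cell to
// the class with lineage q + y.  Uses R's RNG so set.seed() governs runs.

#include <Rcpp.h>
#include <map>
#include <vector>

using namespace Rcpp;

// status codes: 1 target hit (stopped), 2 extinct, 3 censored at t_max,
// 4 censored at pop_cap
// [[Rcpp::export]]
List ssa_run_cpp(NumericVector alpha, NumericVector beta,
                 IntegerVector edge_from, IntegerVector edge_to,
                 NumericVector edge_nu,
                 int root, int target, double z,
                 double t_max, double pop_cap,
                 bool stop_at_target,
                 NumericVector record_times) {
  const int nv = alpha.size();
  const int ne = edge_from.size();

  // adjacency: outgoing edges per vertex
  std::vector<std::vector<int>> out_to(nv);
  std::vector<std::vector<double>> out_nu(nv);
  std::vector<double> nu_tot(nv, 0.0), per_cell(nv, 0.0);
  for (int e = 0; e < ne; ++e) {
    out_to[edge_from[e]].push_back(edge_to[e]);
    out_nu[edge_from[e]].push_back(edge_nu[e]);
    nu_tot[edge_from[e]] += edge_nu[e];
  }
  for (int v = 0; v < nv; ++v) per_cell[v] = alpha[v] + beta[v] + nu_tot[v];

  // lineage classes
  std::vector<std::vector<int>> lineage;
  std::vector<double> count, crate;
  std::vector<int> cvertex;
  std::map<std::vector<int>, int> index;

  std::vector<int> root_lin(1, root);
  lineage.push_back(root_lin);
  count.push_back(z);
  cvertex.push_back(root);
  crate.push_back(z * per_cell[root]);
  index[root_lin] = 0;

  std::vector<double> zv(nv, 0.0);  // per-vertex totals
  zv[root] = z;
  double total_pop = z;
  double total_rate = crate[0];

  const int nrec = record_times.size();
  NumericMatrix snapshots(nrec, nv);
  std::fill(snapshots.begin(), snapshots.end(), NA_REAL);
  int rt_idx = 0;

  // first arrival time per distinct target lineage
  std::vector<int> arrival_class;
  std::vector<double> arrival_time;

  double t = 0.0, t_hit = NA_REAL;
  int seed_class = -1;
  int status = 3;  // default: censored at t_max
  long long it = 0;

  for (;;) {
    if (total_pop <= 0.0) {  // extinction: counts stay zero forever
      while (rt_idx < nrec) {
        for (int v = 0; v < nv; ++v) snapshots(rt_idx, v) = 0.0;
        ++rt_idx;
      }
      status = 2;
      break;
    }
    if (total_rate <= 0.0) {  // frozen population (all per-cell rates zero)
      while (rt_idx < nrec && record_times[rt_idx] <= t_max) {
        for (int v = 0; v < nv; ++v) snapshots(rt_idx, v) = zv[v];
        ++rt_idx;
      }
      t = t_max;
      status = 3;
      break;
    }
    if ((++it % 16384) == 0) {  // curb floating drift in the cached total
      total_rate = 0.0;
      for (size_t c = 0; c < crate.size(); ++c) total_rate += crate[c];
      Rcpp::checkUserInterrupt();
    }
    double t_new = t + exp_rand() / total_rate;
    while (rt_idx < nrec && record_times[rt_idx] <= t_new &&
           record_times[rt_idx] <= t_max) {
      for (int v = 0; v < nv; ++v) snapshots(rt_idx, v) = zv[v];
      ++rt_idx;
    }
    if (t_new > t_max) { t = t_max; status = 3; break; }
    t = t_new;

    // pick class proportionally to its rate
    double u = unif_rand() * total_rate;
    int ci = -1;
    double acc = 0.0;
    for (size_t c = 0; c < crate.size(); ++c) {
      acc += crate[c];
      if (u <= acc) { ci = (int)c; break; }
    }
    if (ci < 0) ci = (int)crate.size() - 1;  // guard against roundoff
    const int v = cvertex[ci];

    // pick event within the class: division | death | transition along edge
    double ue = unif_rand() * per_cell[v];
    if (ue < alpha[v]) {                       // division
      count[ci] += 1.0; zv[v] += 1.0; total_pop += 1.0;
      crate[ci] += per_cell[v]; total_rate += per_cell[v];
      if (total_pop >= pop_cap) { status = 4; break; }
    } else if (ue < alpha[v] + beta[v]) {      // death
      count[ci] -= 1.0; zv[v] -= 1.0; total_pop -= 1.0;
      crate[ci] -= per_cell[v]; total_rate -= per_cell[v];
    } else {                                   // transition (x) -> (x),(y)
      double ut = ue - alpha[v] - beta[v];
      int y = out_to[v].back();
      double acc2 = 0.0;
      for (size_t k = 0; k < out_nu[v].size(); ++k) {
        acc2 += out_nu[v][k];
        if (ut <= acc2) { y = out_to[v][k]; break; }
      }
      std::vector<int> lin = lineage[ci];
      lin.push_back(y);
      int cj;
      std::map<std::vector<int>, int>::iterator hit = index.find(lin);
      if (hit == index.end()) {
        cj = (int)lineage.size();
        index[lin] = cj;
        lineage.push_back(lin);
        count.push_back(0.0);
        cvertex.push_back(y);
        crate.push_back(0.0);
        if (y == target) {
          arrival_class.push_back(cj);
          arrival_time.push_back(t);
        }
      } else {
        cj = hit->second;
      }
      count[cj] += 1.0; zv[y] += 1.0; total_pop += 1.0;
      crate[cj] += per_cell[y]; total_rate += per_cell[y];
      if (y == target && ISNA(t_hit)) {
        t_hit = t;
        seed_class = cj;
        if (stop_at_target) { status = 1; break; }
      }
      if (total_pop >= pop_cap) { status = 4; break; }
    }
  }

  List arrivals(arrival_class.size());
  for (size_t k = 0; k < arrival_class.size(); ++k) {
    arrivals[k] = wrap(lineage[arrival_class[k]]);
  }

  return List::create(
    _["status"] = status,
    _["t_end"] = t,
    _["t_hit"] = t_hit,
    _["seed_lineage"] = seed_class >= 0 ? wrap(lineage[seed_class]) : R_NilValue,
    _["snapshots"] = snapshots,
    _["arrival_lineages"] = arrivals,
    _["arrival_times"] = wrap(arrival_time),
    _["final_counts"] = wrap(zv));
}
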