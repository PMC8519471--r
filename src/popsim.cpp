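#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One cell: per-molecule mRNA translation counters aggregated into bins
// 0..K where K = decay_limit + 1 collects every molecule translated more
// than decay_limit times (the decay-eligible pool), plus a protein tally.
struct Cell {
  std::vector<double> bins;
  double protein;
  explicit Cell(int K) : bins(K + 1, 0.0), protein(0.0) {}
};

static inline double rbinom_safe(double n, double p) {
  if (n <= 0.0 || p <= 0.0) return 0.0;
  if (p >= 1.0) return n;
  return R::rbinom(n, p);
}

// Stochastic protein-production run for one construct at a fixed realized
// opening energy (entering only through the translation-initiation
// probability p_init). Starts from `state` (list with bins matrix, protein
// vector, scale, iteration) or fresh with `initial_cells` empty cells.
// Returns endpoints, the final state, and a thinned trajectory.
// [[Rcpp::export]]
List sim_run_cpp(double p_init, int iterations, List pars,
                 Nullable<List> state_in = R_NilValue,
                 int record_every = 20) {
  const int plasmid_lo = as<int>(pars["plasmid_lo"]);
  const int plasmid_hi = as<int>(pars["plasmid_hi"]);
  const double tx_prob = as<double>(pars["transcription_prob"]);
  const int decay_limit = as<int>(pars["decay_limit"]);
  const double decay_prob = as<double>(pars["decay_prob"]);
  const double tox_threshold = as<double>(pars["toxicity_threshold"]);
  const double repro_prob = as<double>(pars["reproduction_prob"]);
  const double death_prob = as<double>(pars["death_prob"]);
  const double baseline_death = as<double>(pars["baseline_death_prob"]);
  const int initial_cells = as<int>(pars["initial_cells"]);
  const int cap = as<int>(pars["tracked_cap"]);
  const int K = decay_limit + 1;

  std::vector<Cell> cells;
  double scale = 1.0;
  int iter_start = 0;
  if (state_in.isNotNull()) {
    List st(state_in);
    NumericMatrix bins = st["bins"];
    NumericVector protein = st["protein"];
    scale = as<double>(st["scale"]);
    iter_start = as<int>(st["iteration"]);
    if (bins.ncol() != K + 1) stop("state bin count does not match decay_limit");
    for (int i = 0; i < bins.nrow(); ++i) {
      Cell c(K);
      for (int k = 0; k <= K; ++k) c.bins[k] = bins(i, k);
      c.protein = protein[i];
      cells.push_back(c);
    }
  } else {
    cells.assign(initial_cells, Cell(K));
  }

  std::vector<int> traj_iter;
  std::vector<double> traj_cells, traj_mrna, traj_protein;
  auto record = [&](int it) {
    double m = 0.0, p = 0.0;
    for (const Cell& c : cells) {
      p += c.protein;
      for (double b : c.bins) m += b;
    }
    traj_iter.push_back(it);
    traj_cells.push_back(cells.size() * scale);
    traj_mrna.push_back(m * scale);
    traj_protein.push_back(p * scale);
  };

  int it = iter_start;
  const int iter_end = iter_start + iterations;
  bool extinct = cells.empty();
  record(it);
  while (it < iter_end && !cells.empty()) {
    ++it;
    std::vector<Cell> next;
    next.reserve(cells.size() + 8);
    int daughters = 0;
    for (Cell& c : cells) {
      // transcription: plasmid count uniform in [lo, hi], each transcribed
      // with probability tx_prob this round
      int plasmids = plasmid_lo +
        (int)std::floor(unif_rand() * (plasmid_hi - plasmid_lo + 1));
      if (plasmids > plasmid_hi) plasmids = plasmid_hi;
      double new_mrna = rbinom_safe(plasmids, tx_prob);
      // translation: top bin translates in place, lower bins advance
      if (p_init > 0.0) {
        double t_top = rbinom_safe(c.bins[K], p_init);
        c.protein += t_top;
        for (int k = K - 1; k >= 0; --k) {
          if (c.bins[k] <= 0.0) continue;
          double t = rbinom_safe(c.bins[k], p_init);
          if (t > 0.0) {
            c.bins[k] -= t;
            c.bins[k + 1] += t;
            c.protein += t;
          }
        }
      }
      // translation-count-triggered decay of the over-limit pool
      if (c.bins[K] > 0.0 && decay_prob > 0.0) {
        c.bins[K] -= rbinom_safe(c.bins[K], decay_prob);
      }
      c.bins[0] += new_mrna;
      // survival / reproduction
      bool toxic = c.protein > tox_threshold;
      double pd = baseline_death + (toxic ? death_prob : 0.0);
      double u = unif_rand();
      if (u < pd) continue; // cell dies, contents lost
      next.push_back(c);
      if (!toxic && unif_rand() < repro_prob) ++daughters;
    }
    for (int d = 0; d < daughters; ++d) next.push_back(Cell(K));
    cells.swap(next);
    if ((int)cells.size() > cap) {
      // subsample tracked cells, fold the excess into the scale factor
      double ratio = (double)cells.size() / cap;
      for (int i = 0; i < cap; ++i) {
        int j = i + (int)std::floor(unif_rand() * (cells.size() - i));
        if (j >= (int)cells.size()) j = cells.size() - 1;
        std::swap(cells[i], cells[j]);
      }
      cells.erase(cells.begin() + cap, cells.end());
      scale *= ratio;
    }
    if (cells.empty()) {
      extinct = true;
      record(it);
      break;
    }
    if (it % record_every == 0 || it == iter_end) record(it);
  }

  double protein_total = 0.0, mrna_total = 0.0;
  for (const Cell& c : cells) {
    protein_total += c.protein;
    for (double b : c.bins) mrna_total += b;
  }
  int alive = cells.size();
  NumericMatrix bins_out(alive, K + 1);
  NumericVector protein_out(alive);
  for (int i = 0; i < alive; ++i) {
    for (int k = 0; k <= K; ++k) bins_out(i, k) = cells[i].bins[k];
    protein_out[i] = cells[i].protein;
  }

  return List::create(
    _["proteins"] = protein_total * scale,
    _["cells"] = alive * scale,
    _["mrna"] = mrna_total * scale,
    _["proteins_per_cell"] =
      alive > 0 ? protein_total / alive : NA_REAL,
    _["extinct"] = extinct,
    _["iteration"] = it,
    _["state"] = List::create(
      _["bins"] = bins_out, _["protein"] = protein_out,
      _["scale"] = scale, _["iteration"] = it
    ),
    _["trajectory"] = List::create(
      _["iteration"] = traj_iter, _["cells"] = traj_cells,
      _["mrna"] = traj_mrna, _["protein"] = traj_protein
    )
  );
}
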