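#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential best-then-worst multinomial logit log-likelihood, accumulated
// per respondent. `shown` holds 1-based item ids (one row per choice task),
// `best_pos`/`worst_pos` are 1-based positions within the row, `resp` maps
// each row to a row of `beta`. Log-domain throughout: a zero-probability
// event can only arise from non-finite utilities, never from underflow.
// [[Rcpp::export]]
NumericVector cpp_seq_bw_loglik(const NumericMatrix& beta,
                                const IntegerMatrix& shown,
                                const IntegerVector& best_pos,
                                const IntegerVector& worst_pos,
                                const IntegerVector& resp) {
  const int nrow = shown.nrow(), k = shown.ncol();
  const int n = beta.nrow();
  NumericVector out(n);
  std::vector<double> u(k);
  for (int r = 0; r < nrow; ++r) {
    const int i = resp[r] - 1;
    if (i < 0 || i >= n) stop("respondent index out of range");
    const int bp = best_pos[r] - 1, wp = worst_pos[r] - 1;
    double m = -INFINITY;
    for (int j = 0; j < k; ++j) {
      u[j] = beta(i, shown(r, j) - 1);
      if (u[j] > m) m = u[j];
    }
    double se = 0.0;
    for (int j = 0; j < k; ++j) se += std::exp(u[j] - m);
    double ll = (u[bp] - m) - std::log(se);
    double m2 = -INFINITY;
    for (int j = 0; j < k; ++j) if (j != bp && -u[j] > m2) m2 = -u[j];
    double se2 = 0.0;
    for (int j = 0; j < k; ++j) if (j != bp) se2 += std::exp(-u[j] - m2);
    ll += (-u[wp] - m2) - std::log(se2);
    out[i] += ll;
  }
  return out;
}

static inline bool task_contains(const std::vector<int>& tasks, int t, int k,
                                 int item) {
  for (int j = 0; j < k; ++j)
    if (tasks[t * k + j] == item) return true;
  return false;
}

static inline int rand_int(int n) {
  int v = (int)std::floor(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// Random-restart pairwise-swap hill climbing for one questionnaire version.
// Starts are exact in item frequency (r copies of each item dealt into
// tasks, duplicates repaired by frequency-preserving swaps); moves swap two
// items between tasks, so frequency balance is invariant and the objective
// reduces to the sum of squared pair co-occurrence counts, whose minimum
// (attained iff the counts are as equal as integers allow) is returned for
// reference. Uses R's RNG, so results are governed by set.seed().
// [[Rcpp::export]]
List cpp_search_version(int n_items, int set_size, int n_tasks,
                        int n_restarts, int inner_budget, int stall_limit) {
  const int k = set_size, v = n_items;
  const int cells = n_tasks * k;
  const int r = cells / v;
  const long total_pairs = (long)n_tasks * k * (k - 1) / 2;
  const long n_pair_slots = (long)v * (v - 1) / 2;
  const long q = total_pairs / n_pair_slots, rem = total_pairs % n_pair_slots;
  const double min_ss =
      (double)(n_pair_slots - rem) * q * q + (double)rem * (q + 1) * (q + 1);

  std::vector<int> tasks(cells), best_tasks(cells);
  std::vector<int> C((size_t)v * v);
  double best_ss = R_PosInf;

  for (int restart = 0; restart < n_restarts && best_ss > min_ss; ++restart) {
    // construct a start with exact frequencies and no within-task duplicates
    if (k == v) {
      for (int t = 0; t < n_tasks; ++t)
        for (int j = 0; j < k; ++j) tasks[t * k + j] = j + 1;
    } else {
      bool clean = false;
      while (!clean) {
        int idx = 0;
        for (int item = 1; item <= v; ++item)
          for (int c = 0; c < r; ++c) tasks[idx++] = item;
        for (int j = cells - 1; j > 0; --j)
          std::swap(tasks[j], tasks[rand_int(j + 1)]);
        clean = true;
        for (int attempt = 0; attempt < 50 * cells; ++attempt) {
          int t_dup = -1, p_dup = -1;
          for (int t = 0; t < n_tasks && t_dup < 0; ++t)
            for (int p1 = 0; p1 < k && t_dup < 0; ++p1)
              for (int p2 = p1 + 1; p2 < k; ++p2)
                if (tasks[t * k + p1] == tasks[t * k + p2]) {
                  t_dup = t; p_dup = p2; break;
                }
          if (t_dup < 0) break;
          int a = tasks[t_dup * k + p_dup];
          int t2 = rand_int(n_tasks), p2 = rand_int(k);
          int b = tasks[t2 * k + p2];
          if (t2 != t_dup && a != b && !task_contains(tasks, t2, k, a) &&
              !task_contains(tasks, t_dup, k, b)) {
            tasks[t_dup * k + p_dup] = b;
            tasks[t2 * k + p2] = a;
          }
          if (attempt == 50 * cells - 1) clean = false;  // reshuffle
        }
        for (int t = 0; t < n_tasks && clean; ++t)
          for (int p1 = 0; p1 < k && clean; ++p1)
            for (int p2 = p1 + 1; p2 < k; ++p2)
              if (tasks[t * k + p1] == tasks[t * k + p2]) { clean = false; break; }
      }
    }

    std::fill(C.begin(), C.end(), 0);
    for (int t = 0; t < n_tasks; ++t)
      for (int p1 = 0; p1 < k; ++p1)
        for (int p2 = p1 + 1; p2 < k; ++p2) {
          int a = tasks[t * k + p1] - 1, b = tasks[t * k + p2] - 1;
          ++C[a * v + b]; ++C[b * v + a];
        }
    double ss = 0.0;
    for (int a = 0; a < v; ++a)
      for (int b = a + 1; b < v; ++b) ss += (double)C[a * v + b] * C[a * v + b];

    int nonimp = 0;
    for (int it = 0; it < inner_budget && ss > min_ss && nonimp < stall_limit;
         ++it) {
      int t1 = rand_int(n_tasks), t2 = rand_int(n_tasks);
      if (t1 == t2) { ++nonimp; continue; }
      int p1 = rand_int(k), p2 = rand_int(k);
      int a = tasks[t1 * k + p1], b = tasks[t2 * k + p2];
      if (a == b || task_contains(tasks, t1, k, b) ||
          task_contains(tasks, t2, k, a)) { ++nonimp; continue; }
      double delta = 0.0;
      for (int j = 0; j < k; ++j) {
        int c1 = tasks[t1 * k + j];
        if (c1 != a) {
          double ca = C[(a - 1) * v + (c1 - 1)], cb = C[(b - 1) * v + (c1 - 1)];
          delta += (ca - 1) * (ca - 1) - ca * ca + (cb + 1) * (cb + 1) - cb * cb;
        }
        int c2 = tasks[t2 * k + j];
        if (c2 != b) {
          double cb = C[(b - 1) * v + (c2 - 1)], ca = C[(a - 1) * v + (c2 - 1)];
          delta += (cb - 1) * (cb - 1) - cb * cb + (ca + 1) * (ca + 1) - ca * ca;
        }
      }
      if (delta < 0) {
        for (int j = 0; j < k; ++j) {
          int c1 = tasks[t1 * k + j];
          if (c1 != a) {
            --C[(a - 1) * v + (c1 - 1)]; --C[(c1 - 1) * v + (a - 1)];
            ++C[(b - 1) * v + (c1 - 1)]; ++C[(c1 - 1) * v + (b - 1)];
          }
          int c2 = tasks[t2 * k + j];
          if (c2 != b) {
            --C[(b - 1) * v + (c2 - 1)]; --C[(c2 - 1) * v + (b - 1)];
            ++C[(a - 1) * v + (c2 - 1)]; ++C[(c2 - 1) * v + (a - 1)];
          }
        }
        tasks[t1 * k + p1] = b;
        tasks[t2 * k + p2] = a;
        ss += delta;
        nonimp = 0;
      } else {
        ++nonimp;
      }
    }
    if (ss < best_ss) {
      best_ss = ss;
      best_tasks = tasks;
    }
  }

  IntegerMatrix out(n_tasks, k);
  for (int t = 0; t < n_tasks; ++t)
    for (int j = 0; j < k; ++j) out(t, j) = best_tasks[t * k + j];
  return List::create(_["tasks"] = out, _["pair_ss"] = best_ss,
                      _["min_pair_ss"] = min_ss);
}
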