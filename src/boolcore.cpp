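// Core kernels: exact stable-state enumeration by branch-and-propagate,
// and continuous-time (Gillespie) simulation of the asynchronous dynamics.
//
// Rules arrive compiled to postfix token vectors: a token >= 0 pushes the
// value of that node (0-based index); -1 = NOT, -2 = AND, -3 = OR pop their
// operands. Inputs (free constants) have no rule and are represented by
// NULL entries in the token list.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// Three-valued (Kleene) evaluation: 0 = false, 1 = true, 2 = unknown.
// On fully assigned states this reduces to ordinary Boolean evaluation.
int eval3(const std::vector<int>& tok, const std::vector<signed char>& val) {
  static thread_local std::vector<int> stack;
  if (stack.size() < tok.size() + 1) stack.resize(tok.size() + 1);
  int sp = 0;
  for (int t : tok) {
    if (t >= 0) {
      stack[sp++] = val[t];
    } else if (t == -1) {
      int a = stack[sp - 1];
      stack[sp - 1] = (a == 2) ? 2 : 1 - a;
    } else if (t == -2) {
      int b = stack[--sp], a = stack[sp - 1];
      stack[sp - 1] = (a == 0 || b == 0) ? 0 : ((a == 1 && b == 1) ? 1 : 2);
    } else {
      int b = stack[--sp], a = stack[sp - 1];
      stack[sp - 1] = (a == 1 || b == 1) ? 1 : ((a == 0 && b == 0) ? 0 : 2);
    }
  }
  return stack[0];
}

struct TokenModel {
  int n;
  std::vector<std::vector<int>> rules;
  std::vector<char> has_rule;

  explicit TokenModel(const List& tokens) {
    n = tokens.size();
    rules.resize(n);
    has_rule.assign(n, 0);
    for (int i = 0; i < n; ++i) {
      RObject el = tokens[i];
      if (el.isNULL()) continue;
      IntegerVector tv(el);
      rules[i].assign(tv.begin(), tv.end());
      has_rule[i] = 1;
    }
  }
};

struct Solver {
  const TokenModel& m;
  std::vector<char> clamped;
  std::vector<std::vector<signed char>> out;

  Solver(const TokenModel& model, const IntegerVector& clamp_idx)
      : m(model), clamped(model.n, 0) {
    for (int i = 0; i < clamp_idx.size(); ++i) clamped[clamp_idx[i]] = 1;
  }

  // Assign every rule whose value is already determined by the partial
  // assignment; fail on contradiction with an already assigned node.
  bool propagate(std::vector<signed char>& val) {
    bool changed = true;
    while (changed) {
      changed = false;
      for (int i = 0; i < m.n; ++i) {
        if (clamped[i] || !m.has_rule[i]) continue;
        int v = eval3(m.rules[i], val);
        if (v == 2) continue;
        if (val[i] == 2) {
          val[i] = static_cast<signed char>(v);
          changed = true;
        } else if (val[i] != v) {
          return false;
        }
      }
    }
    return true;
  }

  void solve(std::vector<signed char> val) {
    if (!propagate(val)) return;
    int b = -1;
    for (int i = 0; i < m.n; ++i)
      if (val[i] == 2) { b = i; break; }
    if (b < 0) {
      out.push_back(val);
      return;
    }
    std::vector<signed char> v0(val);
    v0[b] = 0;
    solve(std::move(v0));
    val[b] = 1;
    solve(std::move(val));
  }
};

// SplitMix64: seeds one independent, reproducible stream per trajectory.
uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() { s = splitmix64(s + 0x2545F4914F6CDD1DULL); return s; }
  // uniform on [0, 1); 53-bit mantissa, platform independent
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

}  // namespace

// Enumerate all stable states of the model under the given clamps:
// assignments where every non-clamped ruled node equals its rule value,
// clamped nodes hold their forced bit and inputs take any value.
// [[Rcpp::export]]
IntegerMatrix cpp_stable_states(List tokens, IntegerVector clamp_idx,
                                IntegerVector clamp_val) {
  TokenModel m(tokens);
  Solver solver(m, clamp_idx);
  std::vector<signed char> val(m.n, 2);
  for (int i = 0; i < clamp_idx.size(); ++i)
    val[clamp_idx[i]] = static_cast<signed char>(clamp_val[i]);
  solver.solve(std::move(val));

  IntegerMatrix res(solver.out.size(), m.n);
  for (size_t r = 0; r < solver.out.size(); ++r)
    for (int c = 0; c < m.n; ++c) res(r, c) = solver.out[r][c];
  return res;
}

// Gillespie simulation of the asynchronous dynamics. Every eligible single
// node flip carries rate rate_up (0 -> 1) or rate_down (1 -> 0); waiting
// times are exponential in the total rate. init_fixed: per node -1 for an
// i.i.d. uniform initial bit, 0/1 for a fixed one (clamped nodes must
// already be folded in as fixed).
// [[Rcpp::export]]
List cpp_simulate(List tokens, IntegerVector clamp_idx, IntegerVector init_fixed,
                  int n_traj, double rate_up, double rate_down, double max_time,
                  double seed) {
  TokenModel m(tokens);
  std::vector<char> clamped(m.n, 0);
  for (int i = 0; i < clamp_idx.size(); ++i) clamped[clamp_idx[i]] = 1;

  IntegerMatrix finals(n_traj, m.n);
  NumericVector end_time(n_traj);
  LogicalVector absorbed(n_traj);

  const uint64_t master = static_cast<uint64_t>(seed);
  std::vector<int> flip_node;
  std::vector<double> flip_rate;
  flip_node.reserve(m.n);
  flip_rate.reserve(m.n);

  for (int tr = 0; tr < n_traj; ++tr) {
    Rng rng(splitmix64(master) ^ splitmix64(static_cast<uint64_t>(tr) * 0x9E3779B97F4A7C15ULL));
    std::vector<signed char> st(m.n);
    for (int i = 0; i < m.n; ++i)
      st[i] = (init_fixed[i] >= 0) ? static_cast<signed char>(init_fixed[i])
                                   : static_cast<signed char>(rng.unif() < 0.5);
    double t = 0.0;
    bool abs_flag = false;
    for (;;) {
      flip_node.clear();
      flip_rate.clear();
      double total = 0.0;
      for (int i = 0; i < m.n; ++i) {
        if (clamped[i] || !m.has_rule[i]) continue;
        int v = eval3(m.rules[i], st);
        if (v != st[i]) {
          double r = (v == 1) ? rate_up : rate_down;
          flip_node.push_back(i);
          flip_rate.push_back(r);
          total += r;
        }
      }
      if (flip_node.empty()) {
        abs_flag = true;
        break;
      }
      double dt = -std::log(1.0 - rng.unif()) / total;
      if (t + dt > max_time) {
        t = max_time;
        break;
      }
      t += dt;
      double u = rng.unif() * total;
      size_t k = 0;
      double acc = flip_rate[0];
      while (k + 1 < flip_rate.size() && u > acc) acc += flip_rate[++k];
      int nd = flip_node[k];
      st[nd] = static_cast<signed char>(1 - st[nd]);
    }
    for (int i = 0; i < m.n; ++i) finals(tr, i) = st[i];
    end_time[tr] = t;
    absorbed[tr] = abs_flag;
  }

  return List::create(_["final"] = finals, _["end_time"] = end_time,
                      _["absorbed"] = absorbed);
}
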