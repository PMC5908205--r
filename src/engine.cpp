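// Simulation engine: perception (grid + cue cells), competitive Hebbian
// population learning, and the per-timestep trial loop (module proposals,
// hierarchical winner-take-all selection, TD updates of the model-free
// modules and of the gating network). The R-level functions in R/ implement
// the same operations one at a time and are tested against this engine.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Geometry {
  double arena_radius, agent_radius, rmax;
  double grid_gain;
  arma::vec grid_scale, grid_orient, grid_px, grid_py;
  int n_cues, n_cc;
  arma::vec cue_x, cue_y, cue_lambda;
  arma::ivec cue_visible;
  double sigma;
  arma::vec prefs;
  double plat_x, plat_y, plat_r;
  bool plat_present;
  int n_grid() const { return grid_scale.n_elem; }
  int ec_len() const { return n_grid() + n_cues * n_cc; }
};

Geometry unpack_geometry(const List& g) {
  Geometry geo;
  geo.arena_radius = as<double>(g["arena_radius"]);
  geo.agent_radius = as<double>(g["agent_radius"]);
  geo.rmax = geo.arena_radius - geo.agent_radius;
  geo.grid_gain = as<double>(g["grid_gain"]);
  geo.grid_scale = as<arma::vec>(g["grid_scale"]);
  geo.grid_orient = as<arma::vec>(g["grid_orient"]);
  geo.grid_px = as<arma::vec>(g["grid_px"]);
  geo.grid_py = as<arma::vec>(g["grid_py"]);
  geo.n_cues = as<int>(g["n_cues"]);
  geo.n_cc = as<int>(g["n_cc"]);
  geo.cue_x = as<arma::vec>(g["cue_x"]);
  geo.cue_y = as<arma::vec>(g["cue_y"]);
  geo.cue_lambda = as<arma::vec>(g["cue_lambda"]);
  geo.cue_visible = as<arma::ivec>(g["cue_visible"]);
  geo.sigma = as<double>(g["sigma"]);
  geo.prefs = as<arma::vec>(g["prefs"]);
  geo.plat_x = as<double>(g["plat_x"]);
  geo.plat_y = as<double>(g["plat_y"]);
  geo.plat_r = as<double>(g["plat_r"]);
  geo.plat_present = as<bool>(g["plat_present"]);
  return geo;
}

inline double wrap2pi(double a) {
  // same semantics as R's a %% (2*pi)
  const double twopi = 2.0 * M_PI;
  a -= twopi * std::floor(a / twopi);
  if (a >= twopi) a -= twopi;
  if (a < 0) a = 0.0;
  return a;
}

inline double angdiff(double a, double b) {
  double d = wrap2pi(a - b);
  return std::min(d, 2.0 * M_PI - d);
}

// grid + cue-cell activities at a position; fills ec (grid first, then one
// block per cue in cue order). cc_all is the concatenated cue segment view.
void perceive(const Geometry& g, double x, double y, arma::vec& ec) {
  int ng = g.n_grid();
  for (int i = 0; i < ng; ++i) {
    double dx = x - g.grid_px[i], dy = y - g.grid_py[i];
    double k = 4.0 * M_PI / (std::sqrt(3.0) * g.grid_scale[i]);
    double s = 0.0;
    for (int j = 0; j < 3; ++j) {
      double th = g.grid_orient[i] + j * M_PI / 3.0;
      s += std::cos(k * (std::cos(th) * dx + std::sin(th) * dy));
    }
    ec[i] = s > 0 ? g.grid_gain * s / 3.0 : 0.0;
  }
  for (int c = 0; c < g.n_cues; ++c) {
    int off = ng + c * g.n_cc;
    if (!g.cue_visible[c]) {
      for (int m = 0; m < g.n_cc; ++m) ec[off + m] = 0.0;
      continue;
    }
    double dx = g.cue_x[c] - x, dy = g.cue_y[c] - y;
    double dist = std::sqrt(dx * dx + dy * dy);
    double bearing = dist == 0 ? 0.0 : wrap2pi(std::atan2(dy, dx));
    double dec = std::exp(-dist / g.cue_lambda[c]);
    for (int m = 0; m < g.n_cc; ++m) {
      double dth = angdiff(g.prefs[m], bearing);
      ec[off + m] = std::exp(-dth * dth / (2.0 * g.sigma * g.sigma)) * dec;
    }
  }
}

// rectified, k-winner-take-all sparsified, max-normalised population
// activity; k_active <= 0 disables sparsification
void pop_activity(const arma::mat& W, const arma::vec& input, arma::vec& out,
                  int k_active = 0) {
  out = W * input;
  out.transform([](double v) { return v > 0 ? v : 0.0; });
  int n = out.n_elem;
  if (k_active > 0 && k_active < n) {
    // threshold = k-th largest activation (ties by lowest index like R)
    arma::vec tmp = out;
    std::nth_element(tmp.begin(), tmp.begin() + (k_active - 1), tmp.end(),
                     std::greater<double>());
    double thr = tmp[k_active - 1];
    int c_gt = 0;
    for (int i = 0; i < n; ++i) if (out[i] > thr) ++c_gt;
    int slots = k_active - c_gt;  // boundary ties kept at lowest index
    for (int i = 0; i < n; ++i) {
      if (out[i] > thr) continue;
      if (out[i] == thr && slots > 0) { --slots; continue; }
      out[i] = 0.0;
    }
  }
  double m = out.max();
  if (m > 0) out /= m;
}

// competitive Hebbian update of the k most active rows, rows renormalised.
// wins: per-cell win counters; when supplied, each cell learns with an
// annealed rate rate / (1 + wins[i]) so that it converges to the mean of the
// patterns it won (online k-means style) instead of tracking the most recent
// one.
void hebb(arma::mat& W, const arma::vec& pre, const arma::vec& post,
          double rate, int k, std::vector<arma::uword>& idx,
          arma::vec* wins = nullptr) {
  int n = post.n_elem;
  idx.resize(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int kk = std::min(k, n);
  std::partial_sort(idx.begin(), idx.begin() + kk, idx.end(),
                    [&](arma::uword a, arma::uword b) {
                      if (post[a] != post[b]) return post[a] > post[b];
                      return a < b;
                    });
  for (int w = 0; w < kk; ++w) {
    arma::uword i = idx[w];
    double r = rate;
    if (wins) {
      r = rate / (1.0 + (*wins)[i]);
      (*wins)[i] += post[i];
    }
    W.row(i) += r * post[i] * pre.t();
    double nrm = arma::norm(W.row(i), 2);
    if (nrm > 0) W.row(i) /= nrm;
  }
}

}  // namespace

//' Entorhinal input vectors for a set of positions (engine version)
//' @param positions n x 2 matrix of positions (cm).
//' @param geom packed geometry list (see pack_geometry).
//' @return n x ec_length matrix.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix cpp_ec_inputs(const NumericMatrix& positions, const List& geom) {
  Geometry g = unpack_geometry(geom);
  int n = positions.nrow(), L = g.ec_len();
  NumericMatrix out(n, L);
  arma::vec ec(L);
  for (int t = 0; t < n; ++t) {
    perceive(g, positions(t, 0), positions(t, 1), ec);
    for (int j = 0; j < L; ++j) out(t, j) = ec[j];
  }
  return out;
}

//' Competitive Hebbian learning of a population over an input sequence
//' @param W0 initial weight matrix (rows unit norm).
//' @param X input sequence, one row per timestep.
//' @param rate Hebbian learning rate.
//' @param k number of winners per update.
//' @return the trained weight matrix.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix cpp_learn_population(const NumericMatrix& W0,
                                   const NumericMatrix& X, double rate,
                                   int k, int k_active = 0,
                                   bool anneal = true) {
  arma::mat W = as<arma::mat>(W0);
  arma::mat Xm = as<arma::mat>(X);
  arma::vec a(W.n_rows), x(W.n_cols);
  arma::vec wins(W.n_rows, arma::fill::zeros);
  std::vector<arma::uword> idx;
  for (arma::uword t = 0; t < Xm.n_rows; ++t) {
    x = Xm.row(t).t();
    pop_activity(W, x, a, k_active);
    hebb(W, x, a, rate, k, idx, anneal ? &wins : nullptr);
  }
  return wrap(W);
}

//' Rectified max-normalised population activity for an input sequence
//' @param W weight matrix (n_cells x n_in).
//' @param X input sequence (n x n_in).
//' @return n x n_cells activity matrix.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix cpp_population_activity(const NumericMatrix& W,
                                      const NumericMatrix& X,
                                      int k_active = 0) {
  arma::mat Wm = as<arma::mat>(W);
  arma::mat Xm = as<arma::mat>(X);
  arma::mat out(Xm.n_rows, Wm.n_rows);
  arma::vec a(Wm.n_rows), x(Wm.n_cols);
  for (arma::uword t = 0; t < Xm.n_rows; ++t) {
    x = Xm.row(t).t();
    pop_activity(Wm, x, a, k_active);
    out.row(t) = a.t();
  }
  return wrap(out);
}

//' Competitive Hebbian learning with novelty-gated recruitment
//'
//' Cells are recruited one at a time: whenever the best cosine match of the
//' committed cells to the current input falls below the vigilance threshold,
//' the next uncommitted cell commits to (a normalised copy of) the input.
//' Otherwise the k best-matching committed cells are refined by the annealed
//' competitive Hebbian rule. Uncommitted rows are zero.
//' @param n_cells population size.
//' @param X input sequence (rows).
//' @param rate Hebbian refinement rate.
//' @param k winners refined per step.
//' @param vigilance cosine-similarity threshold for recruitment.
//' @return weight matrix (n_cells x n_in); uncommitted rows zero.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix cpp_learn_population_recruit(int n_cells,
                                           const NumericMatrix& X,
                                           double rate, int k,
                                           double vigilance) {
  arma::mat Xm = as<arma::mat>(X);
  int n_in = Xm.n_cols;
  arma::mat W(n_cells, n_in, arma::fill::zeros);
  arma::vec wins(n_cells, arma::fill::zeros);
  int committed = 0;
  arma::vec x(n_in), a;
  std::vector<arma::uword> idx;
  for (arma::uword t = 0; t < Xm.n_rows; ++t) {
    x = Xm.row(t).t();
    double xn = arma::norm(x, 2);
    if (xn == 0) continue;
    double best = -1.0;
    if (committed > 0) {
      a = W.rows(0, committed - 1) * (x / xn);  // rows unit norm -> cosine
      best = a.max();
    }
    if (best < vigilance && committed < n_cells) {
      W.row(committed) = (x / xn).t();
      wins[committed] = 1.0;
      ++committed;
      continue;
    }
    if (committed == 0) continue;
    // refine the k best-matching committed cells (annealed rates)
    arma::vec post(n_cells, arma::fill::zeros);
    post.subvec(0, committed - 1) = a;
    post.transform([](double v) { return v > 0 ? v : 0.0; });
    double m = post.max();
    if (m > 0) post /= m;
    hebb(W, x, post, rate, k, idx, &wins);
  }
  return wrap(W);
}

//' Hierarchical winner-take-all selection (engine version)
//' @param g gating values.
//' @param valid validity flags per module.
//' @param levels 0 = direction, 1 = top (Planning/Locale), 2 = exploration.
//' @param persistence_active is Exploration persistence running?
//' @return 1-based index of the winning module.
//' @keywords internal
// [[Rcpp::export]]
int cpp_select_module(const NumericVector& g, const LogicalVector& valid,
                      const IntegerVector& levels, bool persistence_active) {
  int n = g.size();
  int expl = -1;
  for (int i = 0; i < n; ++i) if (levels[i] == 2) { expl = i; break; }
  if (persistence_active && expl >= 0) return expl + 1;
  // stage 1: best valid direction module
  int d_best = -1;
  for (int i = 0; i < n; ++i) {
    if (levels[i] == 0 && valid[i] && (d_best < 0 || g[i] > g[d_best])) d_best = i;
  }
  // stage 2 candidates in tie-priority order: top > direction > exploration
  int best = -1;
  double gb = 0;
  for (int pass = 0; pass < 3; ++pass) {
    for (int i = 0; i < n; ++i) {
      bool cand = (pass == 0 && levels[i] == 1 && valid[i]) ||
                  (pass == 1 && i == d_best) ||
                  (pass == 2 && levels[i] == 2 && valid[i]);
      if (cand && (best < 0 || g[i] > gb)) { best = i; gb = g[i]; }
    }
  }
  if (best < 0) stop("no valid proposal to select from");
  return best + 1;
}

//' Run one trial of the simulation loop (engine)
//'
//' Mutates the model-free weight matrices and the gating weights in place.
//' @param geom packed trial geometry.
//' @param map list with W_ec_pc and W_pc_gc, or NULL when the agent has no
//'   cognitive map.
//' @param mf list of model-free modules: each a list(W, input, eta, gamma)
//'   where input is a 0-based cue index or -1 for place-cell input.
//' @param plan_tx,plan_ty,plan_valid per-node planning waypoint table.
//' @param z gating weights (n_input x n_modules), updated in place.
//' @param opts list of scalar options (see run_trial).
//' @return list with the trial record.
//' @keywords internal
// [[Rcpp::export]]
List cpp_run_trial(const List& geom, SEXP map, const List& mf,
                   const NumericVector& plan_tx, const NumericVector& plan_ty,
                   const LogicalVector& plan_valid, const List& opts,
                   NumericMatrix z) {
  Geometry g = unpack_geometry(geom);

  bool has_map = map != R_NilValue;
  arma::mat W_ec_pc, W_pc_gc;
  if (has_map) {
    List m(map);
    W_ec_pc = as<arma::mat>(m["W_ec_pc"]);
    W_pc_gc = as<arma::mat>(m["W_pc_gc"]);
  }

  int n_mf = mf.size();
  std::vector<arma::mat> Wmf;   // share storage with the R matrices (in-place updates)
  Wmf.reserve(n_mf);
  std::vector<NumericMatrix> Wmf_r(n_mf);
  std::vector<int> mf_input(n_mf);
  std::vector<double> mf_eta(n_mf), mf_gamma(n_mf);
  for (int i = 0; i < n_mf; ++i) {
    List m = mf[i];
    Wmf_r[i] = as<NumericMatrix>(m["W"]);
    Wmf.emplace_back(Wmf_r[i].begin(), Wmf_r[i].nrow(), Wmf_r[i].ncol(), false, true);
    mf_input[i] = as<int>(m["input"]);
    mf_eta[i] = as<double>(m["eta"]);
    mf_gamma[i] = as<double>(m["gamma"]);
  }
  int n_ac = n_mf > 0 ? Wmf_r[0].nrow() : 36;

  IntegerVector levels = opts["levels"];      // per module
  IntegerVector mf_index = opts["mf_index"];  // per module, -1 if none (1-based from R -> here 0-based or -1)
  int n_mod = levels.size();
  bool goal_set = as<bool>(opts["goal_set"]);
  double eta_g = as<double>(opts["eta_g"]);
  double gamma_g = as<double>(opts["gamma_g"]);
  double step_len = as<double>(opts["step_len"]);
  int max_steps = as<int>(opts["max_steps"]);
  bool record_steps = as<bool>(opts["record_steps"]);
  bool learn_guided = as<bool>(opts["learn_guided"]);
  bool guided_enabled = as<bool>(opts["guided"]);
  double x = as<double>(opts["start_x"]);
  double y = as<double>(opts["start_y"]);
  double expl_phi = as<double>(opts["expl_orientation"]);
  int expl_rem = as<int>(opts["expl_steps_remaining"]);
  int pc_active = as<int>(opts["pc_active"]);
  int gc_active = as<int>(opts["gc_active"]);

  arma::mat zm(z.begin(), z.nrow(), z.ncol(), false);
  int n_in = z.nrow();
  int ng = g.n_grid();

  arma::vec ec_t(g.ec_len()), ec_n(g.ec_len());
  arma::vec pc_t, pc_n, gc_t, gc_n, pchat_t, pchat_n;
  if (has_map) {
    pc_t.set_size(W_ec_pc.n_rows); pc_n.set_size(W_ec_pc.n_rows);
    gc_t.set_size(W_pc_gc.n_rows); gc_n.set_size(W_pc_gc.n_rows);
  }
  arma::vec r_t(n_in), r_n(n_in);
  std::vector<arma::vec> a_t(n_mf), a_n(n_mf);
  for (int i = 0; i < n_mf; ++i) { a_t[i].set_size(n_ac); a_n[i].set_size(n_ac); }
  arma::vec gval(n_mod), gval_n(n_mod);
  std::vector<double> prop_phi(n_mod);
  std::vector<bool> prop_valid(n_mod);
  int node_t = -1;

  // perception at a position -> ec, pc, gc, node, gating input
  auto sense = [&](double px, double py, arma::vec& ec, arma::vec& pc,
                   arma::vec& gc, arma::vec& r, int& node) {
    perceive(g, px, py, ec);
    if (has_map) {
      pop_activity(W_ec_pc, ec, pc, pc_active);
      pop_activity(W_pc_gc, pc, gc, gc_active);
      node = gc.index_max();
    }
    for (int j = 0; j < g.n_cues * g.n_cc; ++j) r[j] = ec[ng + j];
    if (has_map) for (arma::uword j = 0; j < gc.n_elem; ++j) r[g.n_cues * g.n_cc + j] = gc[j];
  };

  auto on_plat = [&](double px, double py) {
    if (!g.plat_present) return false;
    double dx = px - g.plat_x, dy = py - g.plat_y;
    return std::sqrt(dx * dx + dy * dy) <= g.plat_r;
  };

  int total_cap = max_steps + 120;  // guided slack
  NumericMatrix steps_rec;
  NumericMatrix prop_rec;
  if (record_steps) {
    steps_rec = NumericMatrix(total_cap, 5);  // x, y, selected, phi_exec, guided
    prop_rec = NumericMatrix(total_cap, n_mod);
  }
  IntegerVector sel_counts(n_mod);

  bool rewarded = false, was_guided = false;
  int latency = 0, n_rec = 0;

  sense(x, y, ec_t, pc_t, gc_t, r_t, node_t);

  if (on_plat(x, y)) {
    // start position already on the platform
    List out = List::create(
        _["latency"] = 0, _["rewarded"] = true, _["guided"] = false,
        _["sel_counts"] = sel_counts, _["final_node"] = has_map ? node_t + 1 : NA_INTEGER,
        _["expl_orientation"] = expl_phi, _["expl_steps_remaining"] = expl_rem,
        _["n_rec"] = 0, _["steps"] = R_NilValue, _["proposals"] = R_NilValue);
    return out;
  }

  int t = 0, guided_steps = 0;
  bool guiding = false;
  while (true) {
    if (!guiding && t >= max_steps) {
      if (guided_enabled && g.plat_present && !rewarded) {
        guiding = true;
        was_guided = true;
      } else break;
    }
    if (guiding && (rewarded || guided_steps >= 120)) break;

    // --- proposals ---
    bool expl_fresh = false;
    for (int kmod = 0; kmod < n_mod; ++kmod) {
      int mi = mf_index[kmod];
      if (mi >= 0) {
        bool has_input;
        if (mf_input[mi] < 0) {
          // place-based model-free input is unit-normalised (divisive gain
          // control) so the TD step size is scale-free and stable
          double nrm = arma::norm(pc_t, 2);
          pchat_t = nrm > 0 ? arma::vec(pc_t / nrm) : pc_t;
          a_t[mi] = Wmf[mi] * pchat_t;
          has_input = arma::any(pc_t > 0);
        } else {
          auto seg = ec_t.subvec(ng + mf_input[mi] * g.n_cc,
                                 ng + (mf_input[mi] + 1) * g.n_cc - 1);
          a_t[mi] = Wmf[mi] * seg;
          has_input = arma::any(seg > 0);
        }
        prop_phi[kmod] = 2.0 * M_PI * a_t[mi].index_max() / n_ac;
        // a silent input population (invisible cue) carries no information:
        // the module cannot propose an orientation
        prop_valid[kmod] = has_input;
      } else if (levels[kmod] == 1) {  // planning
        bool v = goal_set && node_t >= 0 && plan_valid[node_t];
        prop_valid[kmod] = v;
        prop_phi[kmod] = v ? wrap2pi(std::atan2(plan_ty[node_t] - y,
                                                plan_tx[node_t] - x))
                           : 0.0;
      } else {  // exploration
        if (expl_rem > 0) {
          prop_phi[kmod] = expl_phi;
        } else {
          expl_phi = R::runif(0.0, 2.0 * M_PI);
          prop_phi[kmod] = expl_phi;
          expl_fresh = true;
        }
        prop_valid[kmod] = true;
      }
    }

    // --- gating values and selection ---
    gval = zm.t() * r_t;
    LogicalVector vflag(n_mod);
    NumericVector gv(n_mod);
    for (int kmod = 0; kmod < n_mod; ++kmod) { vflag[kmod] = prop_valid[kmod]; gv[kmod] = gval[kmod]; }
    int sel = cpp_select_module(gv, vflag, levels, expl_rem > 0) - 1;

    double phi_exec;
    if (guiding) {
      phi_exec = std::atan2(g.plat_y - y, g.plat_x - x);
    } else {
      phi_exec = prop_phi[sel];
    }

    // --- move (slide along wall) ---
    double nx = x + step_len * std::cos(phi_exec);
    double ny = y + step_len * std::sin(phi_exec);
    double r2 = std::sqrt(nx * nx + ny * ny);
    if (r2 > g.rmax) { nx *= g.rmax / r2; ny *= g.rmax / r2; }

    int node_n = -1;
    sense(nx, ny, ec_n, pc_n, gc_n, r_n, node_n);
    double R = on_plat(nx, ny) ? 1.0 : 0.0;
    bool terminal = R == 1.0;

    bool learn = !guiding || learn_guided;
    if (learn) {
      // model-free updates: executed orientation mapped to nearest action cell
      for (int mi = 0; mi < n_mf; ++mi) {
        if (mf_input[mi] < 0) {
          double nrm_n = arma::norm(pc_n, 2);
          pchat_n = nrm_n > 0 ? arma::vec(pc_n / nrm_n) : pc_n;
          a_n[mi] = Wmf[mi] * pchat_n;
        } else {
          a_n[mi] = Wmf[mi] * ec_n.subvec(ng + mf_input[mi] * g.n_cc,
                                          ng + (mf_input[mi] + 1) * g.n_cc - 1);
        }
        int istar = 0;
        double bd = 1e18;
        for (int i = 0; i < n_ac; ++i) {
          double d = angdiff(2.0 * M_PI * i / n_ac, phi_exec);
          if (d < bd - 1e-15) { bd = d; istar = i; }
        }
        double target = R + (terminal ? 0.0 : mf_gamma[mi] * a_n[mi].max());
        double delta = target - a_t[mi][istar];
        if (mf_input[mi] < 0) {
          Wmf[mi].row(istar) += mf_eta[mi] * delta * pchat_t.t();
        } else {
          Wmf[mi].row(istar) += mf_eta[mi] * delta *
            ec_t.subvec(ng + mf_input[mi] * g.n_cc,
                        ng + (mf_input[mi] + 1) * g.n_cc - 1).t();
        }
      }
      // gating update, generalised by the cosine of the angular difference
      gval_n = zm.t() * r_n;
      double target_g = R + (terminal ? 0.0 : gamma_g * gval_n.max());
      double delta_g = target_g - gval[sel];
      for (int kmod = 0; kmod < n_mod; ++kmod) {
        if (!prop_valid[kmod]) continue;
        double kap = std::cos(prop_phi[kmod] - phi_exec);
        zm.col(kmod) += eta_g * kap * delta_g * r_t;
      }
    }

    // exploration persistence bookkeeping (consumed only when executed)
    if (!guiding && levels[sel] == 2) {
      if (expl_fresh) expl_rem = 2;
      else if (expl_rem > 0) expl_rem -= 1;
    }

    if (record_steps && n_rec < total_cap) {
      steps_rec(n_rec, 0) = nx; steps_rec(n_rec, 1) = ny;
      steps_rec(n_rec, 2) = sel + 1; steps_rec(n_rec, 3) = phi_exec;
      steps_rec(n_rec, 4) = guiding ? 1.0 : 0.0;
      for (int kmod = 0; kmod < n_mod; ++kmod) {
        prop_rec(n_rec, kmod) = prop_valid[kmod] ? prop_phi[kmod] : NA_REAL;
      }
      ++n_rec;
    }

    if (!guiding) {
      sel_counts[sel] += 1;
      ++t;
    } else {
      ++guided_steps;
    }

    x = nx; y = ny;
    ec_t = ec_n; r_t = r_n; node_t = node_n;
    if (has_map) { pc_t = pc_n; gc_t = gc_n; }

    if (terminal) { rewarded = true; break; }
  }

  latency = rewarded && !was_guided ? t : std::min(t, max_steps);

  // write back possibly-updated MF weights (arma may have reallocated never;
  // aux-memory mats share storage with R, nothing to do). z likewise.
  List out = List::create(
      _["latency"] = latency, _["rewarded"] = rewarded,
      _["guided"] = was_guided, _["sel_counts"] = sel_counts,
      _["final_node"] = has_map ? node_t + 1 : NA_INTEGER,
      _["expl_orientation"] = expl_phi,
      _["expl_steps_remaining"] = expl_rem, _["n_rec"] = n_rec,
      _["steps"] = record_steps ? (SEXP)steps_rec : R_NilValue,
      _["proposals"] = record_steps ? (SEXP)prop_rec : R_NilValue);
  return out;
}
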