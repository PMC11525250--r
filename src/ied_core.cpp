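#include <Rcpp.h>
using namespace Rcpp;

// Model codes: 1 = fRL, 2 = Ca-fRL, 3 = Sa-fRL.
//
// Trial matrices use one fixed layout (0 = absent feature):
//   col 0 stage (1..9), col 1 trial within stage (1-based),
//   col 2 left_rel,  col 3 left_irr,  col 4 right_rel, col 5 right_irr,
//   col 6 choice (1 = left, 2 = right), col 7 feedback (+1 / -1)
// "rel"/"irr" index the *initially* relevant / irrelevant dimension; feature
// ids are 1-based indices into the weight vector.

static inline double sigmoid(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// log(1/(1+exp(-x))), stable for large |x|
static inline double log_logistic(double x) {
  if (x > 0) return -std::log1p(std::exp(-x));
  return x - std::log1p(std::exp(x));
}

struct ModelPar {
  int model;      // 1, 2, 3
  double alpha;   // feature learning rate
  double eps;     // dimension learning rate (Sa-fRL)
  double beta;    // inverse temperature
  double theta0;  // dimension primacy
};

static ModelPar make_par(int model, const double* p) {
  ModelPar mp;
  mp.model = model;
  mp.alpha = p[0];
  if (model == 3) { mp.eps = p[1]; mp.beta = p[2]; mp.theta0 = p[3]; }
  else if (model == 2) { mp.eps = p[0]; mp.beta = p[1]; mp.theta0 = p[2]; }
  else { mp.eps = p[0]; mp.beta = p[1]; mp.theta0 = 0.0; }
  return mp;
}

// Stimulus value. Single-dimension stages (f_irr == 0) bypass attention.
static inline double stim_value(const ModelPar& mp, const std::vector<double>& W,
                                double theta, int f_rel, int f_irr) {
  double wr = (f_rel > 0) ? W[f_rel - 1] : 0.0;
  if (f_irr == 0) return wr;
  double wi = W[f_irr - 1];
  if (mp.model == 1) return wr + wi;
  double a = sigmoid(theta);
  return a * wr + (1.0 - a) * wi;
}

// One gradient pass for one stimulus toward `target`; weights and theta read
// at pre-pass values (single simultaneous step).
static inline void update_pass(const ModelPar& mp, std::vector<double>& W,
                               double& theta, int f_rel, int f_irr, double target) {
  if (f_irr == 0) {  // simple-discrimination stage: no attention, theta frozen
    double d = target - W[f_rel - 1];
    W[f_rel - 1] += mp.alpha * d;
    return;
  }
  double wr = W[f_rel - 1], wi = W[f_irr - 1];
  if (mp.model == 1) {
    double d = target - (wr + wi);
    W[f_rel - 1] += mp.alpha * d;
    W[f_irr - 1] += mp.alpha * d;
  } else {
    double a = sigmoid(theta);
    double d = target - (a * wr + (1.0 - a) * wi);
    W[f_rel - 1] += mp.alpha * d * a;
    W[f_irr - 1] += mp.alpha * d * (1.0 - a);
    double th_lr = (mp.model == 3) ? mp.eps : mp.alpha;
    theta += th_lr * d * (wr - wi) * a * (1.0 - a);
  }
}

// Factual pass on the chosen stimulus (target = R) then counterfactual pass on
// the unchosen stimulus (target = -R); theta evolves through both passes.
static inline void update_trial(const ModelPar& mp, std::vector<double>& W,
                                double& theta, int c_rel, int c_irr,
                                int u_rel, int u_irr, double feedback) {
  update_pass(mp, W, theta, c_rel, c_irr, feedback);
  update_pass(mp, W, theta, u_rel, u_irr, -feedback);
}

// [[Rcpp::export]]
double cpp_nll(int model, NumericVector par, IntegerMatrix trials, int n_features) {
  ModelPar mp = make_par(model, REAL(par));
  std::vector<double> W(n_features, 0.0);
  double theta = mp.theta0;
  double nll = 0.0;
  int n = trials.nrow();
  for (int t = 0; t < n; ++t) {
    int lr = trials(t, 2), li = trials(t, 3);
    int rr = trials(t, 4), ri = trials(t, 5);
    int choice = trials(t, 6);
    double fb = trials(t, 7);
    double vl = stim_value(mp, W, theta, lr, li);
    double vr = stim_value(mp, W, theta, rr, ri);
    double x = mp.beta * ((choice == 1) ? (vl - vr) : (vr - vl));
    nll -= log_logistic(x);
    if (choice == 1) update_trial(mp, W, theta, lr, li, rr, ri, fb);
    else             update_trial(mp, W, theta, rr, ri, lr, li, fb);
  }
  return nll;
}

// Vectorised over parameter rows (columns: native parameters for `model`);
// used by iBIC sampling.
// [[Rcpp::export]]
NumericVector cpp_nll_many(int model, NumericMatrix par, IntegerMatrix trials,
                           int n_features) {
  int K = par.nrow();
  NumericVector out(K);
  std::vector<double> p(par.ncol());
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < par.ncol(); ++j) p[j] = par(k, j);
    NumericVector pv(p.begin(), p.end());
    out[k] = cpp_nll(model, pv, trials, n_features);
  }
  return out;
}

// Simulate one full session. `task` has 9 rows with columns:
//   0 compound (0/1), 1 rel1, 2 rel2, 3 irr1, 4 irr2 (0 if absent), 5 target
// Uses R's RNG (seed with set.seed() in R). Draw order per trial:
// pairing, side, choice.
// [[Rcpp::export]]
List cpp_simulate(int model, NumericVector par, IntegerMatrix task, int n_features,
                  int criterion_run, int trial_cap, bool record_state) {
  ModelPar mp = make_par(model, REAL(par));
  std::vector<double> W(n_features, 0.0);
  double theta = mp.theta0;

  std::vector<int> rows;  // flat trial records, 8 ints each
  std::vector<double> trace;
  IntegerVector errors(9, NA_INTEGER);
  LogicalVector present(9);
  bool failed = false;
  int stages_completed = 0;

  for (int s = 0; s < 9 && !failed; ++s) {
    int compound = task(s, 0);
    int rel1 = task(s, 1), rel2 = task(s, 2);
    int irr1 = task(s, 3), irr2 = task(s, 4);
    int target = task(s, 5);
    present[s] = true;
    int run = 0, ntr = 0, errs = 0;
    while (run < criterion_run && ntr < trial_cap) {
      ++ntr;
      // pairing of irrelevant-dimension features (uniform over both), then side
      int a_irr = 0, b_irr = 0;
      if (compound) {
        bool swap = unif_rand() < 0.5;
        a_irr = swap ? irr2 : irr1;
        b_irr = swap ? irr1 : irr2;
      }
      int l_rel, l_irr, r_rel, r_irr;
      if (unif_rand() < 0.5) { l_rel = rel1; l_irr = a_irr; r_rel = rel2; r_irr = b_irr; }
      else                   { l_rel = rel2; l_irr = b_irr; r_rel = rel1; r_irr = a_irr; }
      double vl = stim_value(mp, W, theta, l_rel, l_irr);
      double vr = stim_value(mp, W, theta, r_rel, r_irr);
      double p_left = sigmoid(mp.beta * (vl - vr));
      int choice = (unif_rand() < p_left) ? 1 : 2;
      int c_rel = (choice == 1) ? l_rel : r_rel;
      int c_irr = (choice == 1) ? l_irr : r_irr;
      int u_rel = (choice == 1) ? r_rel : l_rel;
      int u_irr = (choice == 1) ? r_irr : l_irr;
      int fb = (c_rel == target || c_irr == target) ? 1 : -1;
      if (fb == 1) ++run; else { run = 0; ++errs; }
      update_trial(mp, W, theta, c_rel, c_irr, u_rel, u_irr, (double)fb);
      int rec[8] = { s + 1, ntr, l_rel, l_irr, r_rel, r_irr, choice, fb };
      rows.insert(rows.end(), rec, rec + 8);
      if (record_state) {
        trace.push_back(theta);
        for (int f = 0; f < n_features; ++f) trace.push_back(W[f]);
      }
    }
    errors[s] = errs;
    if (run >= criterion_run) ++stages_completed; else failed = true;
  }

  int n = rows.size() / 8;
  IntegerMatrix trials(n, 8);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 8; ++j) trials(i, j) = rows[i * 8 + j];

  List out = List::create(
    _["trials"] = trials, _["errors"] = errors, _["present"] = present,
    _["stages_completed"] = stages_completed, _["failed"] = failed);
  if (record_state) {
    NumericMatrix st(n, n_features + 1);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j <= n_features; ++j) st(i, j) = trace[i * (n_features + 1) + j];
    out["state"] = st;
  }
  return out;
}
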