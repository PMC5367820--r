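#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven simulation of the n-stage clonal expansion CTMC.
// Compartments Y_1 .. Y_{n-1}: normal cells seed Y_1 as a homogeneous
// Poisson process of rate nu*X (X constant, cells not consumed).
// Preinitiation mutations are asymmetric: a Y_i cell spawns a Y_{i+1}
// daughter at rate mu_i and itself persists (counting process, no
// division or death before initiation) — this is what makes nu*X the
// asymptote of the 3-/4-stage hazards. Cells in the last compartment
// Y_{n-1} (initiated) divide at alpha, die at beta, and convert to
// malignancy at mu_{n-1}. The replicate ends at the first malignant
// cell, at t_max, or at the event cap.
//
// Returns an n_reps x 2 matrix: column 0 the event/censoring time, column
// 1 the status (1 = malignancy, 0 = censored at t_max, 2 = censored at the
// event cap).
// [[Rcpp::export]]
NumericMatrix msce_ctmc_sim(int n_stages, double nu, double X,
                            NumericVector mu, double alpha, double beta,
                            double t_max, int n_reps, double event_cap) {
  if (n_stages < 2 || n_stages > 4)
    stop("n_stages must be 2, 3, or 4");
  if (mu.size() != n_stages - 1)
    stop("mu must have n_stages - 1 entries");
  const double nuX = nu * X;
  const double mu_last = mu[n_stages - 2];
  NumericMatrix out(n_reps, 2);

  for (int rep = 0; rep < n_reps; ++rep) {
    double t = 0.0;
    double y1 = 0.0, y2 = 0.0;   // preinitiation compartments (n >= 3)
    double yl = 0.0;             // initiated (expanding) compartment
    double n_events = 0.0;
    int status = 0;
    double t_end = t_max;

    while (true) {
      double r_pre1 = (n_stages >= 3) ? mu[0] * y1 : 0.0;
      double r_pre2 = (n_stages == 4) ? mu[1] * y2 : 0.0;
      double r_clone = (alpha + beta + mu_last) * yl;
      double total = nuX + r_pre1 + r_pre2 + r_clone;
      if (total <= 0.0) { status = 0; t_end = t_max; break; }
      t += R::exp_rand() / total;
      if (t >= t_max) { status = 0; t_end = t_max; break; }
      n_events += 1.0;
      if (n_events > event_cap) { status = 2; t_end = t; break; }
      double u = unif_rand() * total;
      if (u < nuX) {
        if (n_stages == 2) yl += 1.0; else y1 += 1.0;
      } else if (u < nuX + r_pre1) {
        if (n_stages == 3) yl += 1.0; else y2 += 1.0;   // y1 persists
      } else if (u < nuX + r_pre1 + r_pre2) {
        yl += 1.0;                                      // y2 persists
      } else {
        double v = (u - nuX - r_pre1 - r_pre2) / yl;
        if (v < alpha) yl += 1.0;
        else if (v < alpha + beta) yl -= 1.0;
        else { status = 1; t_end = t; break; }  // first malignant cell
      }
    }
    out(rep, 0) = t_end;
    out(rep, 1) = status;
  }
  return out;
}
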