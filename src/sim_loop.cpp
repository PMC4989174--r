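#include <Rcpp.h>
using namespace Rcpp;

// Frequency-dependent Moran loop with genetic-pool reproduction.
//
// Per period: one group of N is drawn without replacement from the
// (X, Y, Z) population (nested hypergeometric draws), sampled members
// receive the one-shot group payoff, everyone else payoff 0; one
// uniformly chosen individual dies and is replaced by an offspring whose
// type is drawn proportionally to the summed exp(omega * payoff) fitness
// mass of each type; the offspring mutates with probability mu to one of
// the two other types (uniformly).
//
// Uses R's RNG (R::rhyper / unif_rand) in exactly the call order of the
// R reference implementation, so both engines produce bit-identical
// traces from the same seed.
//
// Returns recorded states (period 0 and every record_every-th period),
// running payoff-free summary sums over post-burn-in periods, and corner
// occupancy counts (periods spent within `corner_margin` of each
// monomorphic state) used by the simulation-vs-analytics cross-check.
// [[Rcpp::export]]
List sim_loop_cpp(int M, int N, double c, double r, double alpha,
                  double delta, double gamma, double omega, double mu,
                  int X0, int Y0, int Z0,
                  int periods, int burn_in, int record_every,
                  int corner_margin) {
  int X = X0, Y = Y0, Z = Z0;
  int n_rec = periods / record_every + 1;
  IntegerVector rec_t(n_rec), rec_X(n_rec), rec_Y(n_rec), rec_Z(n_rec);
  int ri = 0;
  rec_t[ri] = 0; rec_X[ri] = X; rec_Y[ri] = Y; rec_Z[ri] = Z; ++ri;

  double sumX = 0, sumY = 0, sumZ = 0;
  double cornerC = 0, cornerD = 0, cornerP = 0;

  for (int t = 1; t <= periods; ++t) {
    // 1. sample the game group
    int xs = (int) R::rhyper(X, Y + Z, N);
    int ds = (int) R::rhyper(Y, Z, N - xs);
    int zs = N - xs - ds;

    // 2. one-shot payoffs for sampled members
    int contrib = xs + zs;
    double share = c * r * std::pow((double) contrib, alpha) / N;
    double PC = share - c;
    double PD = share - delta * zs;
    double PP = share - c - gamma * ds;

    // 3. per-type fitness mass (non-participants have payoff 0, fitness 1)
    double mC = (X - xs) + xs * std::exp(omega * PC);
    double mD = (Y - ds) + ds * std::exp(omega * PD);
    double mP = (Z - zs) + zs * std::exp(omega * PP);

    // 4. genetic-pool update: uniform death, fitness-proportional birth
    double u = unif_rand();
    int die = (u < (double) X / M) ? 0 : (u < (double) (X + Y) / M ? 1 : 2);
    double v = unif_rand() * (mC + mD + mP);
    int born = (v < mC) ? 0 : (v < mC + mD ? 1 : 2);

    // 5. mutation of the newborn
    double w = unif_rand();
    if (w < mu) {
      int o1 = (born == 0) ? 1 : 0;
      int o2 = (born == 2) ? 1 : 2;
      born = (unif_rand() < 0.5) ? o1 : o2;
    }

    if (die == 0) --X; else if (die == 1) --Y; else --Z;
    if (born == 0) ++X; else if (born == 1) ++Y; else ++Z;

    if (t % record_every == 0) {
      rec_t[ri] = t; rec_X[ri] = X; rec_Y[ri] = Y; rec_Z[ri] = Z; ++ri;
    }
    if (t > burn_in) {
      sumX += X; sumY += Y; sumZ += Z;
      if (X >= M - corner_margin) cornerC += 1;
      if (Y >= M - corner_margin) cornerD += 1;
      if (Z >= M - corner_margin) cornerP += 1;
    }
  }

  double span = (double) (periods - burn_in) * M;
  return List::create(
    _["period"] = rec_t, _["X"] = rec_X, _["Y"] = rec_Y, _["Z"] = rec_Z,
    _["mean_freq"] = NumericVector::create(sumX / span, sumY / span,
                                           sumZ / span),
    _["corner_time"] = NumericVector::create(
        cornerC / (periods - burn_in), cornerD / (periods - burn_in),
        cornerP / (periods - burn_in)));
}
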