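// Core numerics for the 4-state (two binary trait) CTMC on a phylogeny:
// generator construction, transition matrices via cached eigendecomposition
// (scaling-and-squaring fallback for defective generators), Felsenstein
// pruning with per-edge rescaling, and the reversible-jump MCMC sampler
// over rate-class partitions with a zero bin.

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Rate slot order used throughout: q12 q13 q21 q24 q31 q34 q42 q43
// States (0-based): 0=(0,0) 1=(0,1) 2=(1,0) 3=(1,1); index = 2*A + B.
static const int QFROM[8] = {0, 0, 1, 1, 2, 2, 3, 3};
static const int QTO[8]   = {1, 2, 0, 3, 0, 3, 1, 2};

static arma::mat generator_k(const arma::vec& q)
{
  arma::mat Q(4, 4, arma::fill::zeros);
  for (int i = 0; i < 8; ++i) Q(QFROM[i], QTO[i]) = q(i);
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

// Eigendecomposition cache for one generator.  P(t) is reconstructed from
// the precomputed tensor W[l](i,j) = U(i,l) * Uinv(l,j) so each branch
// costs k complex exponentials plus k^3 multiply-adds.  When the generator
// is defective (reconstruction error too large) every P(t) falls back to
// scaling-and-squaring (arma::expmat).
struct EigCache {
  int k;
  bool ok;
  arma::mat Q;
  arma::cx_vec lam;
  // flat spectral tensor: W[l*k*k + i*k + j] = U(i,l) * Uinv(l,j), so
  // P(t)(i,j) = Re( sum_l exp(lam_l t) W[l](i,j) ) without allocations
  std::vector<std::complex<double> > W;
  // reach[i*k+j]: is j reachable from i in the rate graph?  P(t) cells for
  // unreachable pairs are structural zeros; round-off leaking into them
  // would turn an impossible transition into one of probability ~1e-12,
  // which corrupts likelihoods whenever rates are exactly zero (as the
  // reversible-jump zero bin routinely makes them).
  std::vector<char> reach;

  void set_reach()
  {
    reach.assign((size_t) k * k, 0);
    for (int i = 0; i < k; ++i) reach[(size_t) i * k + i] = 1;
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        if (i != j && Q(i, j) > 0.0) reach[(size_t) i * k + j] = 1;
    for (int m = 0; m < k; ++m)           // transitive closure
      for (int i = 0; i < k; ++i)
        if (reach[(size_t) i * k + m])
          for (int j = 0; j < k; ++j)
            if (reach[(size_t) m * k + j]) reach[(size_t) i * k + j] = 1;
  }

  void set(const arma::mat& Qin)
  {
    Q = Qin;
    k = Qin.n_rows;
    ok = false;
    set_reach();
    arma::cx_vec lam_;
    arma::cx_mat U;
    if (!arma::eig_gen(lam_, U, Qin)) return;
    arma::cx_mat Uinv;
    if (!arma::inv(Uinv, U)) return;
    arma::cx_mat recon = U * arma::diagmat(lam_) * Uinv;
    double err = arma::abs(arma::real(recon) - Qin).max() +
                 arma::abs(arma::imag(recon)).max();
    double scale = std::max(1.0, arma::abs(Qin).max());
    if (err > 1e-9 * scale) return;
    lam = lam_;
    W.assign((size_t) k * k * k, std::complex<double>(0.0, 0.0));
    for (int l = 0; l < k; ++l)
      for (int i = 0; i < k; ++i)
        for (int j = 0; j < k; ++j)
          W[(size_t) l * k * k + i * k + j] = U(i, l) * Uinv(l, j);
    ok = true;
  }

  // fill row-major P[k*k]
  void ptrans_raw(double t, double* P) const
  {
    if (t <= 0.0) {
      for (int i = 0; i < k * k; ++i) P[i] = 0.0;
      for (int i = 0; i < k; ++i) P[i * k + i] = 1.0;
      return;
    }
    if (ok) {
      for (int i = 0; i < k * k; ++i) P[i] = 0.0;
      for (int l = 0; l < k; ++l) {
        const std::complex<double> el = std::exp(lam(l) * t);
        const std::complex<double>* w = &W[(size_t) l * k * k];
        for (int i = 0; i < k * k; ++i)
          P[i] += w[i].real() * el.real() - w[i].imag() * el.imag();
      }
    } else {
      arma::mat Pm = arma::expmat(Q * t);
      for (int i = 0; i < k; ++i)
        for (int j = 0; j < k; ++j)
          P[i * k + j] = Pm(i, j);
    }
    // clamp round-off and enforce structural zeros
    for (int i = 0; i < k * k; ++i) {
      if (!reach[i] || P[i] < 0.0) P[i] = 0.0;
      else if (P[i] > 1.0) P[i] = 1.0;
    }
  }

  void ptrans(double t, arma::mat& P) const
  {
    std::vector<double> buf((size_t) k * k);
    ptrans_raw(t, buf.data());
    P.set_size(k, k);
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        P(i, j) = buf[(size_t) i * k + j];
  }

  // stationary distribution: left eigenvector of the eigenvalue nearest 0;
  // falls back to uniform when the chain is reducible or the decomposition
  // failed
  arma::vec stationary() const
  {
    arma::vec unif(k, arma::fill::value(1.0 / k));
    if (!ok) return unif;
    arma::uword l0 = arma::index_min(arma::abs(lam));
    if (std::abs(lam(l0)) > 1e-8) return unif;
    // solve pi Q = 0 with sum(pi) = 1
    arma::mat A = Q.t();
    A.row(k - 1).ones();
    arma::vec b(k, arma::fill::zeros);
    b(k - 1) = 1.0;
    arma::vec pi;
    if (!arma::solve(pi, A, b)) return unif;
    if (pi.min() < -1e-8) return unif;
    pi.elem(arma::find(pi < 0.0)).zeros();
    double s = arma::accu(pi);
    if (s <= 0.0) return unif;
    return pi / s;
  }
};

// Felsenstein pruning over a postorder edge list (2 x nedge, 0-based node
// ids, tips 0..ntip-1).  Per-edge rescaling guards against underflow.
static double pruning_ll(const arma::umat& edge, const arma::vec& elen,
                         const arma::mat& tipvec, const EigCache& eg,
                         const arma::vec& rootw)
{
  const int k = tipvec.n_rows;
  const int ntip = tipvec.n_cols;
  const int nedge = edge.n_cols;
  int nnode = 0;
  for (int e = 0; e < nedge; ++e)
    nnode = std::max(nnode, (int) std::max(edge(0, e), edge(1, e)));
  nnode += 1;

  std::vector<double> part((size_t) k * nnode, 1.0);
  for (int i = 0; i < ntip; ++i)
    for (int s = 0; s < k; ++s)
      part[(size_t) i * k + s] = tipvec(s, i);

  double logscale = 0.0;
  std::vector<double> P((size_t) k * k);
  std::vector<double> down((size_t) k);
  for (int e = 0; e < nedge; ++e) {
    const int par = edge(0, e), ch = edge(1, e);
    eg.ptrans_raw(elen(e), P.data());
    const double* pc = &part[(size_t) ch * k];
    double s = 0.0;
    for (int i = 0; i < k; ++i) {
      double acc = 0.0;
      const double* Pi = &P[(size_t) i * k];
      for (int j = 0; j < k; ++j) acc += Pi[j] * pc[j];
      down[i] = acc;
      if (acc > s) s = acc;
    }
    if (!(s > 0.0)) return -arma::datum::inf;
    logscale += std::log(s);
    double* pp = &part[(size_t) par * k];
    for (int i = 0; i < k; ++i) pp[i] *= down[i] / s;
  }
  const int root = edge(0, nedge - 1);
  double L = 0.0;
  for (int i = 0; i < k; ++i) L += rootw(i) * part[(size_t) root * k + i];
  if (!(L > 0.0)) return -arma::datum::inf;
  return std::log(L) + logscale;
}

// [[Rcpp::export]]
double cpp_pruning_loglik(const arma::umat& edge, const arma::vec& elen,
                          const arma::mat& tipvec, const arma::mat& Q,
                          int root_mode, const arma::vec& rootw_custom)
{
  EigCache eg;
  eg.set(Q);
  arma::vec rootw;
  if (root_mode == 0)
    rootw = arma::vec(Q.n_rows,
                      arma::fill::value(1.0 / (double) Q.n_rows));
  else if (root_mode == 1)
    rootw = eg.stationary();
  else
    rootw = rootw_custom;
  return pruning_ll(edge, elen, tipvec, eg, rootw);
}

// [[Rcpp::export]]
arma::mat cpp_transition_matrix(const arma::mat& Q, double t)
{
  EigCache eg;
  eg.set(Q);
  arma::mat P(Q.n_rows, Q.n_rows);
  eg.ptrans(t, P);
  return P;
}

// [[Rcpp::export]]
arma::vec cpp_stationary(const arma::mat& Q)
{
  EigCache eg;
  eg.set(Q);
  return eg.stationary();
}

// ---------------------------------------------------------------------------
// Reversible-jump MCMC over rate-class partitions with a zero bin.
//
// Labels 0..nlab-1 are the free rate parameters (8 dependent, 4
// independent).  `labmap` maps each of the 8 generator slots to a label, or
// -9 for a slot fixed at `fixedvals`.  A partition assigns every label to
// the zero bin (-1) or to one of the value bins; each value bin carries one
// positive rate with prior Exponential(mean m), m ~ Uniform(lo, hi).  The
// partition prior is uniform over structures, so the structure-move
// acceptance reduces to the likelihood ratio times N(s)/N(s') where N
// counts the atomic moves available from a structure (new bin values are
// proposed from their prior).
// ---------------------------------------------------------------------------

struct SamplerState {
  std::vector<int> assign;        // per label: -1 zero bin, else bin index
  std::vector<double> vals;       // one positive value per bin
  double m;
};

static void materialize(const SamplerState& st, const IntegerVector& labmap,
                        const NumericVector& fixedvals, arma::vec& q)
{
  for (int s = 0; s < 8; ++s) {
    if (labmap[s] == -9) q(s) = fixedvals[s];
    else {
      int b = st.assign[labmap[s]];
      q(s) = (b < 0) ? 0.0 : st.vals[b];
    }
  }
}

static long count_moves(const SamplerState& st, int nlab)
{
  int nb = (int) st.vals.size();
  int nz = 0;
  std::vector<int> binsize(nb, 0);
  for (int l = 0; l < nlab; ++l) {
    if (st.assign[l] < 0) ++nz;
    else ++binsize[st.assign[l]];
  }
  long n = 0;
  n += (long) (nlab - nz);            // send a label to the zero bin
  n += (long) nz * (nb + 1);          // resurrect into an existing/new bin
  n += (long) nb * (nb - 1) / 2;      // merge two bins
  for (int b = 0; b < nb; ++b)        // split a bin (unordered bipartitions)
    if (binsize[b] >= 2) n += (1L << (binsize[b] - 1)) - 1L;
  return n;
}

// remove bin b if empty, renumbering assignments above it
static void drop_if_empty(SamplerState& st, int b)
{
  for (size_t l = 0; l < st.assign.size(); ++l)
    if (st.assign[l] == b) return;
  st.vals.erase(st.vals.begin() + b);
  for (size_t l = 0; l < st.assign.size(); ++l)
    if (st.assign[l] > b) --st.assign[l];
}

// Execute the r-th atomic structure move (0 <= r < count_moves(st)).
// New bin values are drawn from Exponential(mean m).
static void do_move(SamplerState& st, int nlab, long r)
{
  int nb = (int) st.vals.size();
  std::vector<int> zl, vl;
  for (int l = 0; l < nlab; ++l)
    (st.assign[l] < 0 ? zl : vl).push_back(l);

  // 1) zero moves
  if (r < (long) vl.size()) {
    int l = vl[r];
    int b = st.assign[l];
    st.assign[l] = -1;
    drop_if_empty(st, b);
    return;
  }
  r -= (long) vl.size();

  // 2) resurrection moves
  long nres = (long) zl.size() * (nb + 1);
  if (r < nres) {
    int l = zl[r / (nb + 1)];
    int t = (int) (r % (nb + 1));
    if (t == nb) {
      st.vals.push_back(R::rexp(st.m));
      st.assign[l] = nb;
    } else st.assign[l] = t;
    return;
  }
  r -= nres;

  // 3) merges (unordered pairs in lexicographic order)
  long nmerge = (long) nb * (nb - 1) / 2;
  if (r < nmerge) {
    int j = 0, kk = 1;
    long c = r;
    for (j = 0; j < nb; ++j) {
      long row = nb - 1 - j;
      if (c < row) { kk = j + 1 + (int) c; break; }
      c -= row;
    }
    for (int l = 0; l < nlab; ++l)
      if (st.assign[l] == kk) st.assign[l] = j;
    st.vals[j] = R::rexp(st.m);
    st.vals.erase(st.vals.begin() + kk);
    for (int l = 0; l < nlab; ++l)
      if (st.assign[l] > kk) --st.assign[l];
    return;
  }
  r -= nmerge;

  // 4) splits: for bin of size b there are 2^(b-1)-1 bipartitions; the
  // lowest-indexed member stays, bits of the code route the rest
  for (int b = 0; b < nb; ++b) {
    std::vector<int> members;
    for (int l = 0; l < nlab; ++l)
      if (st.assign[l] == b) members.push_back(l);
    if (members.size() < 2) continue;
    long nsplit = (1L << (members.size() - 1)) - 1L;
    if (r < nsplit) {
      long code = r + 1;
      int newbin = (int) st.vals.size();
      st.vals[b] = R::rexp(st.m);          // fresh values for both halves
      st.vals.push_back(R::rexp(st.m));
      for (size_t i = 1; i < members.size(); ++i)
        if ((code >> (i - 1)) & 1L) st.assign[members[i]] = newbin;
      return;
    }
    r -= nsplit;
  }
  Rcpp::stop("internal error: RJ move index out of range");
}

// [[Rcpp::export]]
List cpp_rj_sampler(const arma::umat& edge, const arma::vec& elen,
                    const arma::mat& tipvec,
                    const IntegerVector& labmap,
                    const NumericVector& fixedvals,
                    int nlab,
                    int iterations, int burnin, int thin,
                    bool rj, int root_mode, double beta_power,
                    double hyper_lo, double hyper_hi,
                    double prop_scale, double m_prop_sd,
                    const IntegerVector& init_assign,
                    const NumericVector& init_vals,
                    double init_m,
                    bool tune)
{
  RNGScope scope;

  SamplerState st;
  st.assign = std::vector<int>(init_assign.begin(), init_assign.end());
  st.vals = std::vector<double>(init_vals.begin(), init_vals.end());
  st.m = init_m;

  arma::vec q(8);
  EigCache eg;
  auto loglik = [&](const SamplerState& s) -> double {
    arma::vec qq(8);
    materialize(s, labmap, fixedvals, qq);
    arma::mat Q = generator_k(qq);
    eg.set(Q);
    arma::vec rootw = (root_mode == 1) ? eg.stationary()
                                       : arma::vec(4, arma::fill::value(0.25));
    return pruning_ll(edge, elen, tipvec, eg, rootw);
  };

  double ll = loglik(st);
  if (!std::isfinite(ll))
    Rcpp::stop("non-finite log-likelihood at sampler initialization");

  const int nsamp = (iterations - burnin) / thin;
  arma::mat out_q(nsamp, 8);
  arma::vec out_ll(nsamp), out_m(nsamp);
  IntegerMatrix out_assign(nsamp, nlab);

  long val_acc = 0, val_try = 0, rj_acc = 0, rj_try = 0, m_acc = 0, m_try = 0;
  long win_acc = 0, win_try = 0;
  int isamp = 0;

  for (int it = 0; it < iterations; ++it) {
    // -- value update (one random bin, multiplicative log-normal walk)
    if (!st.vals.empty()) {
      int j = (int) std::floor(unif_rand() * st.vals.size());
      if (j >= (int) st.vals.size()) j = (int) st.vals.size() - 1;
      double v = st.vals[j];
      double vp = v * std::exp(prop_scale * norm_rand());
      SamplerState stp = st;
      stp.vals[j] = vp;
      double llp = loglik(stp);
      double la = beta_power * (llp - ll) - (vp - v) / st.m + std::log(vp / v);
      ++val_try; ++win_try;
      if (std::isfinite(llp) && std::log(unif_rand()) < la) {
        st = stp; ll = llp; ++val_acc; ++win_acc;
      }
      if (tune && it < burnin && win_try >= 100) {
        double rate = (double) win_acc / (double) win_try;
        prop_scale *= std::exp(0.5 * (rate - 0.3));
        if (prop_scale < 0.01) prop_scale = 0.01;
        if (prop_scale > 10.0) prop_scale = 10.0;
        win_acc = win_try = 0;
      }
    }

    // -- subset scale move: multiply a random subset of bin values by a
    //    common factor; traverses correlated rate directions (e.g. gain and
    //    loss of one trait moving down together) that single-bin walks
    //    cross only through a likelihood barrier
    if (!st.vals.empty()) {
      SamplerState stp = st;
      double c = std::exp(0.5 * norm_rand());
      double sumv = 0.0;
      int nsel = 0;
      for (double& v : stp.vals)
        if (unif_rand() < 0.5) { sumv += v; v *= c; ++nsel; }
      if (nsel > 0) {
        double llp = loglik(stp);
        double la = beta_power * (llp - ll) - (c - 1.0) * sumv / st.m +
                    (double) nsel * std::log(c);
        if (std::isfinite(llp) && std::log(unif_rand()) < la) {
          st = stp; ll = llp;
        }
      }
    }

    // -- hyperprior mean update (reflective normal walk in (lo, hi));
    //    no likelihood term, only the exponential prior of the bin values
    {
      double mp = st.m + m_prop_sd * norm_rand();
      for (int guard = 0; guard < 64; ++guard) {
        if (mp < hyper_lo) mp = 2.0 * hyper_lo - mp;
        else if (mp > hyper_hi) mp = 2.0 * hyper_hi - mp;
        else break;
      }
      if (mp > hyper_lo && mp < hyper_hi) {
        double la = 0.0;
        for (double v : st.vals)
          la += (-v / mp - std::log(mp)) - (-v / st.m - std::log(st.m));
        ++m_try;
        if (std::log(unif_rand()) < la) { st.m = mp; ++m_acc; }
      }
    }

    // -- reversible-jump structure move
    if (rj) {
      long N = count_moves(st, nlab);
      long r = (long) std::floor(unif_rand() * (double) N);
      if (r >= N) r = N - 1;
      SamplerState stp = st;
      do_move(stp, nlab, r);
      long N2 = count_moves(stp, nlab);
      double llp = loglik(stp);
      double la = beta_power * (llp - ll) +
                  std::log((double) N) - std::log((double) N2);
      ++rj_try;
      if (std::isfinite(llp) && std::log(unif_rand()) < la) {
        st = stp; ll = llp; ++rj_acc;
      }
    }

    if (it >= burnin && ((it - burnin) % thin) == (thin - 1) &&
        isamp < nsamp) {
      materialize(st, labmap, fixedvals, q);
      out_q.row(isamp) = q.t();
      out_ll(isamp) = ll;
      out_m(isamp) = st.m;
      for (int l = 0; l < nlab; ++l) out_assign(isamp, l) = st.assign[l];
      ++isamp;
    }
  }

  return List::create(
    _["samples"] = out_q,
    _["logl"] = out_ll,
    _["m"] = out_m,
    _["assign"] = out_assign,
    _["accept"] = NumericVector::create(
      _["value"] = val_try ? (double) val_acc / val_try : NA_REAL,
      _["hyper"] = m_try ? (double) m_acc / m_try : NA_REAL,
      _["rj"] = rj_try ? (double) rj_acc / rj_try : NA_REAL),
    _["prop_scale"] = prop_scale,
    _["final_assign"] = IntegerVector(st.assign.begin(), st.assign.end()),
    _["final_vals"] = NumericVector(st.vals.begin(), st.vals.end()),
    _["final_m"] = st.m,
    _["final_logl"] = ll);
}
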