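// Structured-coalescent engine for a two-deme divergence model family:
//   epoch 0: [0, T1)  deme sizes N1_0, N2_0
//   epoch 1: [T1, T2) deme sizes N1_1, N2_1
//   epoch 2: [T2, inf) demes merged into one ancestral deme of size N_ANC
// Sizes are DIPLOID effective sizes; a deme of size N holds 2N gene copies,
// so k lineages coalesce at rate choose(k,2)/(2N) per generation.
// Migration window codes: 0 none, 1 = [0,T2), 2 = [T1,T2), 3 = [0,T1).
// Nm values are forward-in-time migrant gene copies per generation into the
// recipient deme; backward in time a lineage in deme i jumps to deme j at
// rate Nm_ij / (2 N_i(t)).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct TreeSim {
  int n1g, n2g, ntips, nnodes;
  std::vector<double> times;
  std::vector<int> parent, left, right, c1, c2;
  int nmig;
  double total_len;

  TreeSim(int n1, int n2) : n1g(n1), n2g(n2), ntips(n1 + n2) {
    nnodes = 2 * ntips - 1;
    times.assign(nnodes, 0.0);
    parent.assign(nnodes, -1);
    left.assign(nnodes, -1);
    right.assign(nnodes, -1);
    c1.assign(nnodes, 0);
    c2.assign(nnodes, 0);
  }

  static int ri(int k) {  // uniform integer in [0, k)
    int i = (int)(unif_rand() * k);
    return i >= k ? k - 1 : i;
  }

  void coalesce(std::vector<int>& deme, double t, int& next) {
    int k = (int)deme.size();
    int ia = ri(k);
    int ib = ri(k - 1);
    if (ib >= ia) ++ib;
    int a = deme[ia], b = deme[ib];
    times[next] = t;
    parent[a] = next;
    parent[b] = next;
    left[next] = a;
    right[next] = b;
    c1[next] = c1[a] + c1[b];
    c2[next] = c2[a] + c2[b];
    // remove a and b, insert the new node
    if (ia > ib) std::swap(ia, ib);
    deme[ia] = next;
    deme[ib] = deme.back();
    deme.pop_back();
    ++next;
  }

  // par: N10 N20 N11 N21 NANC T1 T2 Nm12 Nm21
  void simulate(const double* par, int win) {
    const double N10 = par[0], N20 = par[1], N11 = par[2], N21 = par[3];
    const double NANC = par[4], T1 = par[5], T2 = par[6];
    const double Nm12 = par[7], Nm21 = par[8];

    std::vector<int> d0, d1;
    d0.reserve(ntips);
    d1.reserve(ntips);
    for (int i = 0; i < n1g; ++i) {
      c1[i] = 1;
      d0.push_back(i);
    }
    for (int i = n1g; i < ntips; ++i) {
      c2[i] = 1;
      d1.push_back(i);
    }
    nmig = 0;
    int next = ntips;
    double t = 0.0;

    for (int e = 0; e < 3; ++e) {
      if ((int)d0.size() + (int)d1.size() <= 1) break;
      double N1, N2, m1 = 0.0, m2 = 0.0, tend;
      bool mig;
      if (e == 0) {
        N1 = N10; N2 = N20; tend = T1;
        mig = (win == 1 || win == 3);
      } else if (e == 1) {
        N1 = N11; N2 = N21; tend = T2;
        mig = (win == 1 || win == 2);
      } else {
        // merge: everything coalesces in one ancestral deme
        for (size_t i = 0; i < d1.size(); ++i) d0.push_back(d1[i]);
        d1.clear();
        N1 = NANC; N2 = 1.0; tend = R_PosInf;
        mig = false;
      }
      if (mig) {
        m1 = Nm12 / (2.0 * N1);
        m2 = Nm21 / (2.0 * N2);
      }
      for (;;) {
        int k1 = (int)d0.size(), k2 = (int)d1.size();
        if (k1 + k2 <= 1) break;
        double rc1 = k1 > 1 ? k1 * (k1 - 1) / 2.0 / (2.0 * N1) : 0.0;
        double rc2 = k2 > 1 ? k2 * (k2 - 1) / 2.0 / (2.0 * N2) : 0.0;
        double rm1 = mig ? k1 * m1 : 0.0;
        double rm2 = mig ? k2 * m2 : 0.0;
        double R = rc1 + rc2 + rm1 + rm2;
        if (R <= 0.0) {  // isolated lineages wait for the next epoch
          t = tend;
          break;
        }
        double dt = exp_rand() / R;
        if (t + dt >= tend) {
          t = tend;
          break;
        }
        t += dt;
        double u = unif_rand() * R;
        if (u < rc1) {
          coalesce(d0, t, next);
        } else if (u < rc1 + rc2) {
          coalesce(d1, t, next);
        } else if (u < rc1 + rc2 + rm1) {
          int i = ri(k1);
          d1.push_back(d0[i]);
          d0[i] = d0.back();
          d0.pop_back();
          ++nmig;
        } else {
          int i = ri(k2);
          d0.push_back(d1[i]);
          d1[i] = d1.back();
          d1.pop_back();
          ++nmig;
        }
      }
    }

    total_len = 0.0;
    int root = nnodes - 1;
    for (int v = 0; v < nnodes; ++v) {
      if (v == root) continue;
      total_len += times[parent[v]] - times[v];
    }
  }

  // tip ids (0-based) descending from node v
  void descendants(int v, std::vector<int>& out) const {
    out.clear();
    std::vector<int> stack(1, v);
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      if (u < ntips) {
        out.push_back(u);
      } else {
        stack.push_back(left[u]);
        stack.push_back(right[u]);
      }
    }
  }
};

void check_par(const NumericVector& par, int win) {
  if (par.size() != 9) stop("parameter vector must have length 9");
  for (int i = 0; i < 5; ++i)
    if (!(par[i] > 0)) stop("population sizes must be positive");
  if (!(par[5] > 0 && par[6] > par[5])) stop("need 0 < T1 < T2");
  if (par[7] < 0 || par[8] < 0) stop("Nm must be non-negative");
  if (win < 0 || win > 3) stop("migration window code must be in 0..3");
}

}  // namespace

// Mean branch length per unfolded derived-count cell (i copies in deme 1,
// j copies in deme 2), averaged over nsims genealogies.
// [[Rcpp::export]]
List cpp_branch_sfs(NumericVector par, int win, int n1g, int n2g, int nsims) {
  check_par(par, win);
  if (n1g + n2g < 2) stop("need at least two gene copies");
  NumericMatrix sfs(n1g + 1, n2g + 1);
  double tot = 0.0;
  TreeSim sim(n1g, n2g);
  for (int r = 0; r < nsims; ++r) {
    sim.simulate(REAL(par), win);
    int root = sim.nnodes - 1;
    for (int v = 0; v < sim.nnodes; ++v) {
      if (v == root) continue;
      double bl = sim.times[sim.parent[v]] - sim.times[v];
      sfs(sim.c1[v], sim.c2[v]) += bl;
    }
    tot += sim.total_len;
  }
  for (int i = 0; i <= n1g; ++i)
    for (int j = 0; j <= n2g; ++j) sfs(i, j) /= nsims;
  return List::create(_["lengths"] = sfs, _["total_length"] = tot / nsims);
}

// Simulate nloci independent loci of `len` bp at mutation rate mu per site
// per generation (infinite sites within a locus). Returns the derived-allele
// membership matrix (SNPs x gene copies; deme-1 copies first) and the locus
// index of each SNP.
// [[Rcpp::export]]
List cpp_sim_loci(NumericVector par, int win, int n1g, int n2g, int nloci,
                  double len, double mu) {
  check_par(par, win);
  if (n1g + n2g < 2) stop("need at least two gene copies");
  TreeSim sim(n1g, n2g);
  int ntips = n1g + n2g;
  std::vector<std::vector<int> > snp_tips;
  std::vector<int> snp_locus;
  std::vector<int> tips;
  std::vector<double> cum(sim.nnodes - 1);
  for (int l = 0; l < nloci; ++l) {
    sim.simulate(REAL(par), win);
    int root = sim.nnodes - 1;
    double L = 0.0;
    for (int v = 0; v < root; ++v) {
      L += sim.times[sim.parent[v]] - sim.times[v];
      cum[v] = L;
    }
    int nmut = (int)R::rpois(L * mu * len);
    for (int m = 0; m < nmut; ++m) {
      double x = unif_rand() * L;
      int v = (int)(std::lower_bound(cum.begin(), cum.end(), x) - cum.begin());
      if (v >= root) v = root - 1;
      sim.descendants(v, tips);
      snp_tips.push_back(tips);
      snp_locus.push_back(l + 1);
    }
  }
  int nsnp = (int)snp_tips.size();
  IntegerMatrix memb(nsnp, ntips);
  for (int s = 0; s < nsnp; ++s)
    for (size_t k = 0; k < snp_tips[s].size(); ++k)
      memb(s, snp_tips[s][k]) = 1;
  return List::create(_["membership"] = memb,
                      _["locus"] = IntegerVector(snp_locus.begin(), snp_locus.end()));
}

// Per-replicate TMRCA, total branch length and migration-event count.
// [[Rcpp::export]]
List cpp_sim_tmrca(NumericVector par, int win, int n1g, int n2g, int nsims) {
  check_par(par, win);
  if (n1g + n2g < 2) stop("need at least two gene copies");
  NumericVector tmrca(nsims), tlen(nsims);
  IntegerVector nmig(nsims);
  TreeSim sim(n1g, n2g);
  for (int r = 0; r < nsims; ++r) {
    sim.simulate(REAL(par), win);
    tmrca[r] = sim.times[sim.nnodes - 1];
    tlen[r] = sim.total_len;
    nmig[r] = sim.nmig;
  }
  return List::create(_["tmrca"] = tmrca, _["total_length"] = tlen,
                      _["n_migrations"] = nmig);
}

// One genealogy with full topology: parent pointers (0-based, root = -1),
// node times, per-node descendant counts per deme, migration-event count.
// [[Rcpp::export]]
List cpp_sim_tree(NumericVector par, int win, int n1g, int n2g) {
  check_par(par, win);
  if (n1g + n2g < 2) stop("need at least two gene copies");
  TreeSim sim(n1g, n2g);
  sim.simulate(REAL(par), win);
  return List::create(
      _["parent"] = IntegerVector(sim.parent.begin(), sim.parent.end()),
      _["time"] = NumericVector(sim.times.begin(), sim.times.end()),
      _["n_desc_1"] = IntegerVector(sim.c1.begin(), sim.c1.end()),
      _["n_desc_2"] = IntegerVector(sim.c2.begin(), sim.c2.end()),
      _["n_tips"] = sim.ntips, _["n_migrations"] = sim.nmig,
      _["total_length"] = sim.total_len);
}
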