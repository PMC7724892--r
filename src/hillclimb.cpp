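// Greedy hill-climbing structure search over Gaussian BIC local scores,
// operating on the centered cross-product matrix C = X'X of the data.
// Mirrors the score algebra documented in R/bayesnet.R: per-node score
// deltas for single-parent additions and deletions are obtained from the
// inverse of the current parent block (Schur-complement updates). A
// descendant-reachability matrix, maintained incrementally across moves,
// masks cycle-creating additions up front; reversal validity is checked
// against the same matrix. Ties are broken by a fixed scan order for
// determinism.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double bic_from_rss(double rss, int n_par, double n,
                                  double logn) {
  double sigma2 = std::max(rss, 1e-12) / n;
  return -n / 2.0 * (std::log(2.0 * M_PI * sigma2) + 1.0) -
         logn / 2.0 * (n_par + 2.0);
}

// full transitive closure by depth-first search from every node: O(p * E),
// cheap for the sparse graphs the search moves through
static imat reachability(const imat &amat) {
  const uword p = amat.n_rows;
  // adjacency lists once
  std::vector<std::vector<uword>> kids(p);
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (amat(i, j) == 1) kids[i].push_back(j);
  imat D(p, p, fill::zeros);
  std::vector<uword> stack;
  std::vector<char> seen(p);
  for (uword s = 0; s < p; ++s) {
    std::fill(seen.begin(), seen.end(), 0);
    stack.assign(kids[s].begin(), kids[s].end());
    for (uword k : kids[s]) seen[k] = 1;
    while (!stack.empty()) {
      uword v = stack.back();
      stack.pop_back();
      D(s, v) = 1;
      for (uword k : kids[v])
        if (!seen[k]) { seen[k] = 1; stack.push_back(k); }
    }
    D(s, s) = 0;
  }
  return D;
}

struct DeltaState {
  const mat &C;
  double n, logn, tol;
  imat &amat;
  std::vector<uvec> &pa;
  vec &ls;
  mat &dAdd, &dDel;

  // recompute column j of the add/delete delta caches and ls[j]
  void refresh(uword j) {
    const uword p = C.n_rows;
    double Cjj = C(j, j);
    dAdd.col(j).fill(NEG_INF);
    dDel.col(j).fill(NEG_INF);
    const uvec &paj = pa[j];
    uword npa = paj.n_elem;

    std::vector<uword> candv;
    candv.reserve(p);
    for (uword i = 0; i < p; ++i)
      if (i != j && amat(i, j) == 0) candv.push_back(i);
    uvec cand = conv_to<uvec>::from(candv);

    if (npa == 0) {
      ls[j] = bic_from_rss(Cjj, 0, n, logn);
      for (uword k = 0; k < cand.n_elem; ++k) {
        uword c = cand[k];
        double s = C(c, c);
        if (s <= tol) continue;  // collinear candidate stays -Inf
        double rssA = Cjj - C(c, j) * C(c, j) / s;
        dAdd(c, j) = bic_from_rss(rssA, 1, n, logn) - ls[j];
      }
      return;
    }

    mat A = C.submat(paj, paj);
    mat Ainv;
    if (!inv_sympd(Ainv, A)) {
      // singular parent block: make deletions maximally attractive
      ls[j] = NEG_INF;
      for (uword k = 0; k < npa; ++k)
        dDel(paj[k], j) = std::numeric_limits<double>::infinity();
      return;
    }
    uvec jv = {j};
    vec v = C.submat(paj, jv);
    vec u = Ainv * v;
    double q = dot(v, u);
    double rssF = Cjj - q;
    ls[j] = bic_from_rss(rssF, (int)npa, n, logn);

    vec dgA = Ainv.diag();
    for (uword k = 0; k < npa; ++k) {
      double rssD = Cjj - (q - u[k] * u[k] / dgA[k]);
      dDel(paj[k], j) = bic_from_rss(rssD, (int)npa - 1, n, logn) - ls[j];
    }

    if (cand.n_elem) {
      mat B = C.submat(paj, cand);
      mat AB = Ainv * B;
      rowvec ssum = sum(B % AB, 0);
      rowvec wAdj = C.submat(jv, cand) - u.t() * B;
      for (uword k = 0; k < cand.n_elem; ++k) {
        double s = C(cand[k], cand[k]) - ssum[k];
        if (s <= tol) continue;
        double rssA = rssF - wAdj[k] * wAdj[k] / s;
        dAdd(cand[k], j) = bic_from_rss(rssA, (int)npa + 1, n, logn) - ls[j];
      }
    }
  }
};

// [[Rcpp::export(name = ".hcCoreCpp")]]
Rcpp::List hc_core_cpp(const arma::mat &C, double n,
                       const arma::imat &initAmat, int maxIter) {
  const uword p = C.n_rows;
  imat amat = initAmat;
  std::vector<uvec> pa(p);
  for (uword j = 0; j < p; ++j) pa[j] = find(amat.col(j) == 1);

  vec ls(p, fill::zeros);
  mat dAdd(p, p), dDel(p, p);
  double logn = std::log(n);
  double tol = 1e-10 * C.diag().max();
  DeltaState st{C, n, logn, tol, amat, pa, ls, dAdd, dDel};
  for (uword j = 0; j < p; ++j) st.refresh(j);

  imat D = reachability(amat);

  std::vector<double> traj;
  traj.push_back(accu(ls));
  bool converged = false;
  const double eps = 1e-10;

  for (int iter = 0; iter < maxIter; ++iter) {
    double best = eps;
    int bop = -1;
    uword bi = 0, bj = 0;
    for (uword i = 0; i < p; ++i) {
      for (uword j = 0; j < p; ++j) {
        if (i == j) continue;
        if (amat(i, j) == 0) {
          if (D(j, i) == 0) {  // add i -> j keeps the graph acyclic
            double val = dAdd(i, j);
            if (val > best) { best = val; bop = 0; bi = i; bj = j; }
          }
        } else {
          double del = dDel(i, j);
          if (del > best) { best = del; bop = 1; bi = i; bj = j; }
          double rev = del + dAdd(j, i);
          if (rev > best) {
            // reversing i -> j is legal iff no alternative directed path
            // i ~> j exists: no other child k of i already reaches j
            // (in a DAG such a path cannot itself use the arc i -> j)
            bool alt = false;
            for (uword k = 0; k < p; ++k)
              if (k != j && amat(i, k) == 1 && D(k, j) == 1) {
                alt = true;
                break;
              }
            if (!alt) { best = rev; bop = 2; bi = i; bj = j; }
          }
        }
      }
    }
    // strict > comparisons keep the first candidate in scan order among
    // exact ties: (from, to) cell order, then add < delete < reverse
    // within a cell -- a fixed, deterministic tie-break
    if (bop < 0) { converged = true; break; }

    if (bop == 0) {
      amat(bi, bj) = 1;
      pa[bj] = find(amat.col(bj) == 1);
      st.refresh(bj);
      // incremental closure: (ancestors(i) + i) x (descendants(j) + j)
      ivec anc = D.col(bi); anc[bi] = 1;
      irowvec desc = D.row(bj); desc[bj] = 1;
      D = arma::max(D, anc * desc);
      D.diag().zeros();
    } else if (bop == 1) {
      amat(bi, bj) = 0;
      pa[bj] = find(amat.col(bj) == 1);
      st.refresh(bj);
      D = reachability(amat);
    } else {
      amat(bi, bj) = 0;
      amat(bj, bi) = 1;
      pa[bj] = find(amat.col(bj) == 1);
      pa[bi] = find(amat.col(bi) == 1);
      st.refresh(bi);
      st.refresh(bj);
      D = reachability(amat);
    }
    traj.push_back(accu(ls));
  }

  return Rcpp::List::create(
      Rcpp::Named("amat") = Rcpp::wrap(amat),
      Rcpp::Named("score") = accu(ls),
      Rcpp::Named("trajectory") = traj,
      Rcpp::Named("converged") = converged);
}
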