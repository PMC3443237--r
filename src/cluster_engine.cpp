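// Smallest-ellipsoid cluster search: k-means over the pooled top-M peaks of
// all participants, with each cluster trimmed to at most one peak per
// participant (keeping the peak nearest the centroid, ties broken by better
// rank). Across iterations and restarts the smallest trimmed cluster (by
// major 95% radius) is recorded for every achieved participant count.
// This runs once per permutation of the null, hence C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double Z95 = 1.959963984540054;

// major 95% radius: Z95 * sqrt(largest eigenvalue of the sample covariance)
static double major_radius(const arma::mat& pts) {
  arma::mat C = arma::cov(pts);
  arma::vec ev;
  if (!arma::eig_sym(ev, C)) return arma::datum::inf;
  double m = ev.max();
  return Z95 * std::sqrt(m > 0.0 ? m : 0.0);
}

static int sample_weighted(const arma::vec& w) {
  double tot = arma::accu(w);
  int n = w.n_elem;
  if (tot <= 0.0) return std::min((int)(unif_rand() * n), n - 1);
  double u = unif_rand() * tot, c = 0.0;
  for (int i = 0; i < n; ++i) {
    c += w[i];
    if (u <= c) return i;
  }
  return n - 1;
}

// [[Rcpp::export]]
List cpp_smallest_clusters(const arma::mat& pts, const IntegerVector& pid,
                           const IntegerVector& rank, int k, int n_min,
                           int iters, int restarts) {
  const int n = pts.n_rows;
  int npart = 0;
  for (int i = 0; i < n; ++i) npart = std::max(npart, pid[i]);
  const int nsizes = npart - n_min + 1;
  if (nsizes < 1) stop("n_min exceeds the number of participants");

  arma::vec best_r(nsizes);
  best_r.fill(arma::datum::inf);
  std::vector<std::vector<int> > best_members(nsizes);

  std::vector<int> assign(n), keep_pt(npart), mem;
  std::vector<double> keep_d(npart);
  arma::mat centers(k, 3);

  for (int rs = 0; rs < restarts; ++rs) {
    // k-means++ seeding
    arma::vec d2(n);
    d2.fill(arma::datum::inf);
    int first = std::min((int)(unif_rand() * n), n - 1);
    centers.row(0) = pts.row(first);
    for (int c = 1; c < k; ++c) {
      for (int i = 0; i < n; ++i) {
        double dd = arma::accu(arma::square(pts.row(i) - centers.row(c - 1)));
        if (dd < d2[i]) d2[i] = dd;
      }
      centers.row(c) = pts.row(sample_weighted(d2));
    }

    for (int it = 0; it < iters; ++it) {
      // assign every pooled point to its nearest centroid
      std::vector<double> adist(n);
      for (int i = 0; i < n; ++i) {
        int bj = 0;
        double bd = arma::datum::inf;
        for (int j = 0; j < k; ++j) {
          double dd = arma::accu(arma::square(pts.row(i) - centers.row(j)));
          if (dd < bd) { bd = dd; bj = j; }
        }
        assign[i] = bj;
        adist[i] = bd;
      }
      // trim each cluster to <=1 point per participant, track the best
      for (int j = 0; j < k; ++j) {
        std::fill(keep_pt.begin(), keep_pt.end(), -1);
        for (int i = 0; i < n; ++i) {
          if (assign[i] != j) continue;
          int p = pid[i] - 1;
          if (keep_pt[p] < 0 || adist[i] < keep_d[p] ||
              (adist[i] == keep_d[p] && rank[i] < rank[keep_pt[p]])) {
            keep_pt[p] = i;
            keep_d[p] = adist[i];
          }
        }
        mem.clear();
        for (int p = 0; p < npart; ++p)
          if (keep_pt[p] >= 0) mem.push_back(keep_pt[p]);
        int s = (int)mem.size();
        if (s >= 2) {
          if (s >= n_min) {
            arma::mat mpts(s, 3);
            for (int q = 0; q < s; ++q) mpts.row(q) = pts.row(mem[q]);
            double r = major_radius(mpts);
            if (r < best_r[s - n_min]) {
              best_r[s - n_min] = r;
              best_members[s - n_min] = mem;
            }
          }
          // recompute centroid from the trimmed members
          arma::rowvec ctr(3, arma::fill::zeros);
          for (int q = 0; q < s; ++q) ctr += pts.row(mem[q]);
          centers.row(j) = ctr / s;
        } else if (s == 1) {
          centers.row(j) = pts.row(mem[0]);
        }
        // s == 0: centroid unchanged
      }
    }
  }

  NumericVector radii(nsizes, NA_REAL);
  List members(nsizes);
  for (int s = 0; s < nsizes; ++s) {
    if (std::isfinite(best_r[s])) {
      radii[s] = best_r[s];
      IntegerVector iv(best_members[s].size());
      for (size_t q = 0; q < best_members[s].size(); ++q)
        iv[q] = best_members[s][q] + 1;  // 1-based for R
      members[s] = iv;
    }
  }
  return List::create(_["radii"] = radii, _["members"] = members);
}
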