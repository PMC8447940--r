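#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact Euclidean distance transform on cell centers: for every cell of an
// nr x nc grid, the minimum distance (in meters) from its center to the center
// of any source cell. Brute force over source cells; grids here are at most a
// few hundred cells on a side.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericMatrix edt_cpp(IntegerVector src_row, IntegerVector src_col, int nr,
                      int nc, double cell) {
  const int ns = src_row.size();
  NumericMatrix out(nr, nc);
  if (ns == 0) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  std::vector<double> sr(ns), sc(ns);
  for (int i = 0; i < ns; ++i) {
    sr[i] = (double)src_row[i];
    sc[i] = (double)src_col[i];
  }
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double best = R_PosInf;
      for (int i = 0; i < ns; ++i) {
        const double dr = r - sr[i], dc = c - sc[i];
        const double d2 = dr * dr + dc * dc;
        if (d2 < best) best = d2;
      }
      out(r, c) = std::sqrt(best) * cell;
    }
  }
  return out;
}

// k-nearest-neighbour inverse-distance-weighted interpolation from scattered
// points to query locations, using a uniform spatial hash of the points and an
// expanding-ring search. A query closer than 1e-9 m to a point takes that
// point's value exactly.
// [[Rcpp::export(name = ".knn_idw_cpp")]]
NumericVector knn_idw_cpp(NumericVector px, NumericVector py, NumericVector pv,
                          NumericVector qx, NumericVector qy, int k,
                          double power) {
  const int n = px.size(), nq = qx.size();
  NumericVector out(nq);
  if (n == 0) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  const int kk = std::min(k, n);

  double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
    ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
  }
  double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) span = 1.0;
  // aim for ~1-4 points per bin
  int nb = std::max(1, (int)std::floor(std::sqrt((double)n / 2.0)));
  const double bin = span / nb;
  const int bx = std::max(1, (int)std::floor((xmax - xmin) / bin) + 1);
  const int by = std::max(1, (int)std::floor((ymax - ymin) / bin) + 1);

  std::vector<std::vector<int>> cells((size_t)bx * by);
  auto bin_of = [&](double x, double y) {
    int cx = (int)std::floor((x - xmin) / bin);
    int cy = (int)std::floor((y - ymin) / bin);
    cx = std::min(std::max(cx, 0), bx - 1);
    cy = std::min(std::max(cy, 0), by - 1);
    return std::make_pair(cx, cy);
  };
  for (int i = 0; i < n; ++i) {
    auto b = bin_of(px[i], py[i]);
    cells[(size_t)b.second * bx + b.first].push_back(i);
  }

  std::vector<std::pair<double, int>> cand;
  const int max_ring = std::max(bx, by);
  for (int q = 0; q < nq; ++q) {
    auto b = bin_of(qx[q], qy[q]);
    cand.clear();
    int ring = 0;
    double kth = R_PosInf;
    while (ring <= max_ring) {
      // collect the cells on this ring
      for (int cy = b.second - ring; cy <= b.second + ring; ++cy) {
        if (cy < 0 || cy >= by) continue;
        for (int cx = b.first - ring; cx <= b.first + ring; ++cx) {
          if (cx < 0 || cx >= bx) continue;
          if (std::max(std::abs(cx - b.first), std::abs(cy - b.second)) != ring)
            continue;
          for (int i : cells[(size_t)cy * bx + cx]) {
            const double dx = px[i] - qx[q], dy = py[i] - qy[q];
            cand.push_back({dx * dx + dy * dy, i});
          }
        }
      }
      if ((int)cand.size() >= kk) {
        std::nth_element(cand.begin(), cand.begin() + (kk - 1), cand.end());
        kth = cand[kk - 1].first;
        // any point outside rings searched so far is at least this far away
        const double safe = (double)ring * bin;
        if (safe * safe >= kth) break;
      }
      ++ring;
    }
    const int m = std::min((int)cand.size(), kk);
    std::partial_sort(cand.begin(), cand.begin() + m, cand.end());
    if (m > 0 && cand[0].first < 1e-18) {
      out[q] = pv[cand[0].second];
      continue;
    }
    double num = 0.0, den = 0.0;
    for (int j = 0; j < m; ++j) {
      const double d = std::sqrt(cand[j].first);
      const double wgt = std::pow(d, -power);
      num += wgt * pv[cand[j].second];
      den += wgt;
    }
    out[q] = (den > 0) ? num / den : NA_REAL;
  }
  return out;
}
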