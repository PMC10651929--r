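#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double EARTH_R = 6371000.0;
static const double DEG = M_PI / 180.0;

static inline double hav_m(double lon1, double lat1, double lon2, double lat2) {
  double dlat = (lat2 - lat1) * DEG, dlon = (lon2 - lon1) * DEG;
  double a = std::sin(dlat / 2) * std::sin(dlat / 2) +
             std::cos(lat1 * DEG) * std::cos(lat2 * DEG) *
             std::sin(dlon / 2) * std::sin(dlon / 2);
  if (a > 1.0) a = 1.0;
  return 2.0 * EARTH_R * std::asin(std::sqrt(a));
}

// median of the first n entries of a scratch copy (R stats::median convention:
// mean of the two central order statistics for even n)
static double med(std::vector<double>& scratch, const std::vector<double>& x) {
  size_t n = x.size();
  scratch.assign(x.begin(), x.end());
  size_t h = n / 2;
  std::nth_element(scratch.begin(), scratch.begin() + h, scratch.end());
  double m = scratch[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(scratch.begin(), scratch.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

// Greedy sequential stay clustering of one user's time-sorted pings.
// A candidate ping joins the current cluster iff, after inclusion, the maximum
// haversine distance from any member to the coordinate-wise median centroid is
// strictly below d_roam_m; otherwise the cluster is closed (emitted as a stay
// when it has >= min_events pings and spans >= min_duration_min minutes) and
// the violating ping opens the next cluster.
// [[Rcpp::export]]
DataFrame detect_stays_cpp(NumericVector ts, NumericVector lat,
                           NumericVector lon, double d_roam_m,
                           double min_duration_min, int min_events) {
  int n = ts.size();
  std::vector<double> c_lat, c_lon, c_ts, scratch;
  std::vector<double> out_start, out_end, out_clat, out_clon;
  std::vector<int> out_n;

  auto flush = [&]() {
    int k = (int)c_ts.size();
    if (k >= min_events &&
        (c_ts.back() - c_ts.front()) / 60.0 >= min_duration_min) {
      out_start.push_back(c_ts.front());
      out_end.push_back(c_ts.back());
      out_clat.push_back(med(scratch, c_lat));
      out_clon.push_back(med(scratch, c_lon));
      out_n.push_back(k);
    }
    c_lat.clear(); c_lon.clear(); c_ts.clear();
  };

  for (int i = 0; i < n; ++i) {
    c_lat.push_back(lat[i]); c_lon.push_back(lon[i]); c_ts.push_back(ts[i]);
    if (c_ts.size() > 1) {
      double mlat = med(scratch, c_lat), mlon = med(scratch, c_lon);
      double mx = 0.0;
      for (size_t j = 0; j < c_lat.size(); ++j) {
        double d = hav_m(c_lon[j], c_lat[j], mlon, mlat);
        if (d > mx) mx = d;
      }
      if (mx >= d_roam_m) {
        // violating ping leaves and opens the next cluster
        c_lat.pop_back(); c_lon.pop_back(); c_ts.pop_back();
        flush();
        c_lat.push_back(lat[i]); c_lon.push_back(lon[i]); c_ts.push_back(ts[i]);
      }
    }
  }
  flush();

  return DataFrame::create(_["start"] = wrap(out_start),
                           _["end"] = wrap(out_end),
                           _["centroid_lat"] = wrap(out_clat),
                           _["centroid_lon"] = wrap(out_clon),
                           _["n_pings"] = wrap(out_n));
}

// Nearest POI (haversine) for each stay centroid; returns 1-based POI index,
// or 0 when the nearest POI is at distance >= d_max_m. Ties at equal distance
// go to the smaller index (caller orders POIs by id).
// [[Rcpp::export]]
List nearest_poi_cpp(NumericVector slat, NumericVector slon,
                     NumericVector plat, NumericVector plon, double d_max_m) {
  int ns = slat.size(), np = plat.size();
  IntegerVector idx(ns);
  NumericVector dist(ns);
  for (int i = 0; i < ns; ++i) {
    int best = 0; double bd = R_PosInf;
    for (int j = 0; j < np; ++j) {
      double d = hav_m(slon[i], slat[i], plon[j], plat[j]);
      if (d < bd) { bd = d; best = j + 1; }
    }
    if (np == 0 || bd >= d_max_m) { idx[i] = 0; dist[i] = NA_REAL; }
    else { idx[i] = best; dist[i] = bd; }
  }
  return List::create(_["index"] = idx, _["dist_m"] = dist);
}
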