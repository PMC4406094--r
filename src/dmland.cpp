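#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++, state seeded from a single integer via splitmix64.
// The simulation engine owns its stream so replicates are reproducible from
// (config, seed) alone, independent of R's global RNG state.
// ---------------------------------------------------------------------------
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline bool bern(double p) { return unif() < p; }
  // uniform integer on [0, n); n is tiny relative to 2^53 so bias is nil
  inline int below(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
  // Knuth multiplicative method; fine for the lambdas used here (<= ~10)
  inline int poisson(double lambda) {
    const double L = std::exp(-lambda);
    double p = 1.0; int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
};

// ---------------------------------------------------------------------------
// Uniform bucket grid for fixed-radius neighbour queries.
// ---------------------------------------------------------------------------
struct PointGrid {
  double minx, miny, cell;
  int ncx, ncy;
  std::vector<std::vector<int>> bins;

  PointGrid(const double* x, const double* y, int n, double cell_) {
    cell = cell_ > 0 ? cell_ : 1.0;
    minx = miny = 0.0;
    double maxx = 0.0, maxy = 0.0;
    if (n > 0) {
      minx = maxx = x[0]; miny = maxy = y[0];
      for (int i = 1; i < n; ++i) {
        if (x[i] < minx) minx = x[i];
        if (x[i] > maxx) maxx = x[i];
        if (y[i] < miny) miny = y[i];
        if (y[i] > maxy) maxy = y[i];
      }
    }
    ncx = std::max(1, (int)std::floor((maxx - minx) / cell) + 1);
    ncy = std::max(1, (int)std::floor((maxy - miny) / cell) + 1);
    bins.assign((size_t)ncx * ncy, {});
    for (int i = 0; i < n; ++i) bins[cell_of(x[i], y[i])].push_back(i);
  }
  inline size_t cell_of(double px, double py) const {
    int cx = (int)std::floor((px - minx) / cell);
    int cy = (int)std::floor((py - miny) / cell);
    cx = std::min(std::max(cx, 0), ncx - 1);
    cy = std::min(std::max(cy, 0), ncy - 1);
    return (size_t)cy * ncx + cx;
  }
  // visit every point in the 3x3 block of cells around (px, py)
  template <typename F>
  inline void visit(double px, double py, F&& f) const {
    int cx = (int)std::floor((px - minx) / cell);
    int cy = (int)std::floor((py - miny) / cell);
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = cy + dy;
      if (yy < 0 || yy >= ncy) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = cx + dx;
        if (xx < 0 || xx >= ncx) continue;
        for (int id : bins[(size_t)yy * ncx + xx]) f(id);
      }
    }
  }
};

// ---------------------------------------------------------------------------
// DBSCAN (Ester et al. semantics): a core point has >= minpts points within
// eps, the query point included; clusters are density-reachability closures,
// border points join the first cluster that reaches them under index order.
// Labels: 0 = noise, 1..k = clusters.
// ---------------------------------------------------------------------------
static int dbscan_labels(const std::vector<double>& px,
                         const std::vector<double>& py,
                         double eps, int minpts,
                         std::vector<int>& label) {
  const int n = (int)px.size();
  label.assign(n, -2);               // -2 unclassified, -1 noise
  if (n == 0) return 0;
  PointGrid grid(px.data(), py.data(), n, eps);
  const double eps2 = eps * eps;
  std::vector<int> nbr, seeds;
  auto region_query = [&](int i, std::vector<int>& out) {
    out.clear();
    grid.visit(px[i], py[i], [&](int j) {
      double dx = px[i] - px[j], dy = py[i] - py[j];
      if (dx * dx + dy * dy <= eps2) out.push_back(j);
    });
  };
  int ncl = 0;
  for (int i = 0; i < n; ++i) {
    if (label[i] != -2) continue;
    region_query(i, nbr);
    if ((int)nbr.size() < minpts) { label[i] = -1; continue; }
    ++ncl;
    label[i] = ncl;
    seeds.assign(nbr.begin(), nbr.end());
    for (size_t k = 0; k < seeds.size(); ++k) {
      int q = seeds[k];
      if (label[q] == -1) label[q] = ncl;      // border point
      if (label[q] != -2) continue;
      label[q] = ncl;
      region_query(q, nbr);
      if ((int)nbr.size() >= minpts)
        seeds.insert(seeds.end(), nbr.begin(), nbr.end());
    }
  }
  for (int i = 0; i < n; ++i) if (label[i] == -1) label[i] = 0;
  return ncl;
}

// [[Rcpp::export(name = ".dbscan_cpp")]]
List dbscan_cpp(NumericVector x, NumericVector y, double eps, int minpts) {
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  std::vector<int> label;
  int ncl = dbscan_labels(px, py, eps, minpts, label);
  return List::create(_["labels"] = IntegerVector(label.begin(), label.end()),
                      _["n_clusters"] = ncl);
}

// [[Rcpp::export(name = ".kth_nn_dist_cpp")]]
NumericVector kth_nn_dist_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  NumericVector out(n);
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      d[m++] = dx * dx + dy * dy;
    }
    std::nth_element(d.begin(), d.begin() + (k - 1), d.begin() + m);
    out[i] = std::sqrt(d[k - 1]);
  }
  return out;
}

// [[Rcpp::export(name = ".min_nn_dist_cpp")]]
double min_nn_dist_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}

// All unordered site pairs (1-based indices) within `radius`, grid-accelerated.
// [[Rcpp::export(name = ".neighbor_pairs_cpp")]]
List neighbor_pairs_cpp(NumericVector x, NumericVector y, double radius) {
  const int n = x.size();
  PointGrid grid(REAL(x), REAL(y), n, radius);
  const double r2 = radius * radius;
  std::vector<int> vi, vj;
  std::vector<double> vd;
  for (int i = 0; i < n; ++i) {
    grid.visit(x[i], y[i], [&](int j) {
      if (j <= i) return;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 <= r2) {
        vi.push_back(i + 1); vj.push_back(j + 1); vd.push_back(std::sqrt(d2));
      }
    });
  }
  return List::create(_["i"] = IntegerVector(vi.begin(), vi.end()),
                      _["j"] = IntegerVector(vj.begin(), vj.end()),
                      _["d"] = NumericVector(vd.begin(), vd.end()));
}

// ---------------------------------------------------------------------------
// Simulation engine.
//
// Genome layout: L = 2 + n_neutral diallelic loci, two allele slots per locus
// (uint8, values 0/1). Locus 0: 1 = derived allele "a" (irreversible forward
// mutation A -> a). Locus 1: 1 = derived allele "B" (irreversible backward
// mutation b -> B). Neutral loci: symmetric flip (2-allele k-allele model).
// Two-locus class index: 3 * (#a) + (#B) in 0..8.
//
// Generation cycle: every female draws one mate among males within `radius`
// of her site, inverse-square-weighted with distances floored at d_floor;
// Poisson(lambda) offspring per mated pair with free recombination and
// per-allele mutation at transmission; all adults die; offspring settle in
// uniformly random order on vacant sites within `radius` of the natal site
// (the natal site itself is a candidate at the distance floor); each settler
// survives with probability equal to its two-locus genotype fitness, death
// re-vacating the site; offspring with no vacant site in range, or arriving
// after all sites fill, are discarded.
// ---------------------------------------------------------------------------

// Candidate-set scan threshold: below this, sample by a direct weighted scan
// of the neighbour list; above it, rejection-sample from the static cumulative
// weights (correct conditional distribution) and fall back to a scan.
static const int SCAN_LIMIT = 384;
static const int REJECT_CAP = 40;

// [[Rcpp::export(name = ".sim_replicate_cpp")]]
List sim_replicate_cpp(NumericVector sx, NumericVector sy,
                       double radius, double d_floor,
                       int generations, double lambda, double mu,
                       int n_neutral, NumericVector fitness9,
                       bool detect_ri, double eps, int minpts,
                       double seed) {
  const int n = sx.size();
  const int L = 2 + n_neutral;
  const int A2 = 2 * L;
  const double* X = REAL(sx);
  const double* Y = REAL(sy);
  const double w_self = 1.0 / (d_floor * d_floor);
  Xoshiro rng((uint64_t)seed);

  // --- CSR neighbour lists with inverse-square cumulative weights ---------
  std::vector<size_t> nb_start(n + 1, 0);
  std::vector<int> nb_idx;
  std::vector<double> cumw;            // per-site running sums of 1/d^2
  {
    PointGrid grid(X, Y, n, radius);
    const double r2 = radius * radius;
    for (int i = 0; i < n; ++i) {
      size_t cnt = 0;
      grid.visit(X[i], Y[i], [&](int j) {
        if (j == i) return;
        double dx = X[i] - X[j], dy = Y[i] - Y[j];
        if (dx * dx + dy * dy <= r2) ++cnt;
      });
      nb_start[i + 1] = nb_start[i] + cnt;
    }
    nb_idx.resize(nb_start[n]);
    cumw.resize(nb_start[n]);
    for (int i = 0; i < n; ++i) {
      size_t p = nb_start[i];
      grid.visit(X[i], Y[i], [&](int j) {
        if (j == i) return;
        double dx = X[i] - X[j], dy = Y[i] - Y[j];
        double d2 = dx * dx + dy * dy;
        if (d2 <= r2) {
          double d = std::sqrt(d2);
          if (d < d_floor) d = d_floor;
          nb_idx[p] = j;
          cumw[p] = 1.0 / (d * d);
          ++p;
        }
      });
      double acc = 0.0;
      for (size_t t = nb_start[i]; t < nb_start[i + 1]; ++t) {
        acc += cumw[t];
        cumw[t] = acc;
      }
    }
  }
  auto weight_at = [&](int i, size_t t) {
    return t == nb_start[i] ? cumw[t] : cumw[t] - cumw[t - 1];
  };
  auto total_weight = [&](int i) {
    return nb_start[i + 1] > nb_start[i] ? cumw[nb_start[i + 1] - 1] : 0.0;
  };

  // --- population state ----------------------------------------------------
  std::vector<uint8_t> occ(n, 1), sex(n), geno((size_t)n * A2);
  for (int i = 0; i < n; ++i) {
    sex[i] = rng.bern(0.5);            // 0 = female, 1 = male
    uint8_t* g = &geno[(size_t)i * A2];
    g[0] = g[1] = 0;                   // locus 0: AA
    g[2] = g[3] = 0;                   // locus 1: bb
    for (int t = 4; t < A2; ++t) g[t] = rng.bern(0.5);
  }
  int n_occ = n;

  // --- output --------------------------------------------------------------
  const int NCOL = 17;
  NumericMatrix stats(generations + 1, NCOL);
  std::vector<double> cx, cy;          // coords for DBSCAN per class

  auto record = [&](int g) {
    long het = 0;
    std::vector<long> ones(n_neutral, 0);
    int cls[9] = {0};
    for (int i = 0; i < n; ++i) {
      if (!occ[i]) continue;
      const uint8_t* gg = &geno[(size_t)i * A2];
      int a_cnt = gg[0] + gg[1], B_cnt = gg[2] + gg[3];
      ++cls[3 * a_cnt + B_cnt];
      for (int l = 0; l < n_neutral; ++l) {
        uint8_t a1 = gg[4 + 2 * l], a2 = gg[5 + 2 * l];
        het += (a1 != a2);
        ones[l] += a1 + a2;
      }
    }
    double Ho = NA_REAL, He = NA_REAL, F = NA_REAL;
    if (n_occ > 0 && n_neutral > 0) {
      Ho = (double)het / ((double)n_occ * n_neutral);
      double hesum = 0.0;
      for (int l = 0; l < n_neutral; ++l) {
        double p = (double)ones[l] / (2.0 * n_occ);
        hesum += 2.0 * p * (1.0 - p);
      }
      He = hesum / n_neutral;
      F = He > 0 ? 1.0 - Ho / He : NA_REAL;
    }
    int ncl_AABB = 0, ncl_aabb = 0, flag = 0;
    if (detect_ri && n_occ > 0) {
      std::vector<int> lab;
      cx.clear(); cy.clear();
      for (int i = 0; i < n; ++i) {      // AABB: no a, two B
        if (!occ[i]) continue;
        const uint8_t* gg = &geno[(size_t)i * A2];
        if (gg[0] + gg[1] == 0 && gg[2] + gg[3] == 2) {
          cx.push_back(X[i]); cy.push_back(Y[i]);
        }
      }
      ncl_AABB = dbscan_labels(cx, cy, eps, minpts, lab);
      cx.clear(); cy.clear();
      for (int i = 0; i < n; ++i) {      // aabb: two a, no B
        if (!occ[i]) continue;
        const uint8_t* gg = &geno[(size_t)i * A2];
        if (gg[0] + gg[1] == 2 && gg[2] + gg[3] == 0) {
          cx.push_back(X[i]); cy.push_back(Y[i]);
        }
      }
      ncl_aabb = dbscan_labels(cx, cy, eps, minpts, lab);
      flag = (ncl_AABB >= 1 && ncl_aabb >= 1) ? 1 : 0;
    }
    stats(g, 0) = g;
    stats(g, 1) = n_occ;
    stats(g, 2) = Ho; stats(g, 3) = He; stats(g, 4) = F;
    // column order AABB, AABb, AAbb, AaBB, AaBb, Aabb, aaBB, aaBb, aabb
    stats(g, 5) = cls[2];  stats(g, 6) = cls[1];  stats(g, 7) = cls[0];
    stats(g, 8) = cls[5];  stats(g, 9) = cls[4];  stats(g, 10) = cls[3];
    stats(g, 11) = cls[8]; stats(g, 12) = cls[7]; stats(g, 13) = cls[6];
    stats(g, 14) = ncl_AABB; stats(g, 15) = ncl_aabb; stats(g, 16) = flag;
  };

  record(0);

  // mate draw: weighted among males within radius of female site i
  auto draw_mate = [&](int i) -> int {
    const size_t b = nb_start[i], e = nb_start[i + 1];
    const size_t k = e - b;
    if (k == 0) return -1;
    if ((int)k > SCAN_LIMIT) {
      const double tot = cumw[e - 1];
      for (int t = 0; t < REJECT_CAP; ++t) {
        size_t pos = std::upper_bound(cumw.begin() + b, cumw.begin() + e,
                                      rng.unif() * tot) - cumw.begin();
        if (pos >= e) pos = e - 1;
        int j = nb_idx[pos];
        if (occ[j] && sex[j] == 1) return j;
      }
    }
    double tot = 0.0;
    for (size_t t = b; t < e; ++t) {
      int j = nb_idx[t];
      if (occ[j] && sex[j] == 1) tot += weight_at(i, t);
    }
    if (tot <= 0.0) return -1;
    double r = rng.unif() * tot, acc = 0.0;
    int last = -1;
    for (size_t t = b; t < e; ++t) {
      int j = nb_idx[t];
      if (occ[j] && sex[j] == 1) {
        acc += weight_at(i, t);
        last = j;
        if (r <= acc) return j;
      }
    }
    return last;
  };

  // settlement draw for an offspring born at site s: vacant candidates are
  // s itself (weight w_self) and neighbours within radius; -1 if none vacant
  auto draw_site = [&](int s) -> int {
    const size_t b = nb_start[s], e = nb_start[s + 1];
    const size_t k = e - b;
    if ((int)k > SCAN_LIMIT) {
      const double tot = w_self + cumw[e - 1];
      for (int t = 0; t < REJECT_CAP; ++t) {
        double r = rng.unif() * tot;
        int j;
        if (r < w_self) j = s;
        else {
          size_t pos = std::upper_bound(cumw.begin() + b, cumw.begin() + e,
                                        r - w_self) - cumw.begin();
          if (pos >= e) pos = e - 1;
          j = nb_idx[pos];
        }
        if (!occ[j]) return j;
      }
    }
    double tot = occ[s] ? 0.0 : w_self;
    for (size_t t = b; t < e; ++t)
      if (!occ[nb_idx[t]]) tot += weight_at(s, t);
    if (tot <= 0.0) return -1;
    double r = rng.unif() * tot;
    if (!occ[s]) {
      if (r < w_self) return s;
      r -= w_self;
    }
    double acc = 0.0;
    int last = -1;
    for (size_t t = b; t < e; ++t) {
      int j = nb_idx[t];
      if (!occ[j]) {
        acc += weight_at(s, t);
        last = j;
        if (r <= acc) return j;
      }
    }
    return last;
  };

  // offspring pool
  std::vector<int> onatal;
  std::vector<uint8_t> osex, ogeno;
  std::vector<int> perm;
  const bool do_mut = mu > 0.0;
  int last_gen = generations;
  std::string status = "ok";

  for (int g = 1; g <= generations; ++g) {
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
    onatal.clear(); osex.clear(); ogeno.clear();

    // mate selection + reproduction
    for (int i = 0; i < n; ++i) {
      if (!occ[i] || sex[i] != 0) continue;
      int m = draw_mate(i);
      if (m < 0) continue;
      int brood = rng.poisson(lambda);
      const uint8_t* gm = &geno[(size_t)i * A2];
      const uint8_t* gf = &geno[(size_t)m * A2];
      for (int o = 0; o < brood; ++o) {
        onatal.push_back(i);
        osex.push_back(rng.bern(0.5));
        for (int l = 0; l < L; ++l) {
          uint8_t am = gm[2 * l + (rng.next() & 1)];
          uint8_t af = gf[2 * l + (rng.next() & 1)];
          if (do_mut) {
            if (l < 2) {               // irreversible derived-allele mutation
              if (am == 0 && rng.bern(mu)) am = 1;
              if (af == 0 && rng.bern(mu)) af = 1;
            } else {                   // symmetric flip at neutral loci
              if (rng.bern(mu)) am ^= 1;
              if (rng.bern(mu)) af ^= 1;
            }
          }
          ogeno.push_back(am);
          ogeno.push_back(af);
        }
      }
    }

    // adult mortality (non-overlapping generations)
    std::fill(occ.begin(), occ.end(), 0);
    n_occ = 0;

    // dispersal in uniformly random order, with viability selection
    const int npool = (int)onatal.size();
    perm.resize(npool);
    for (int t = 0; t < npool; ++t) perm[t] = t;
    for (int t = npool - 1; t > 0; --t)
      std::swap(perm[t], perm[rng.below(t + 1)]);
    for (int t = 0; t < npool && n_occ < n; ++t) {
      const int o = perm[t];
      const int site = draw_site(onatal[o]);
      if (site < 0) continue;          // no vacant site in range: discarded
      const uint8_t* og = &ogeno[(size_t)o * A2];
      const double w = fitness9[3 * (og[0] + og[1]) + (og[2] + og[3])];
      if (w < 1.0 && !(w > 0.0 && rng.bern(w))) continue;  // inviable settler
      occ[site] = 1;
      sex[site] = osex[o];
      std::copy(og, og + A2, &geno[(size_t)site * A2]);
      ++n_occ;
    }

    record(g);
    if (n_occ == 0) { last_gen = g; status = "extinct"; break; }
  }

  // final population snapshot
  IntegerVector fsite(n_occ), fsex(n_occ);
  IntegerMatrix fgeno(n_occ, A2);
  for (int i = 0, r = 0; i < n; ++i) {
    if (!occ[i]) continue;
    fsite[r] = i + 1;
    fsex[r] = sex[i];
    for (int t = 0; t < A2; ++t) fgeno(r, t) = geno[(size_t)i * A2 + t];
    ++r;
  }

  return List::create(
    _["stats"] = stats(Range(0, last_gen), _),
    _["status"] = status,
    _["site"] = fsite,
    _["sex"] = fsex,
    _["geno"] = fgeno);
}
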