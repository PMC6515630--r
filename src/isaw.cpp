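// Interacting self-avoiding walk (ISAW) on the simple cubic lattice.
// Metropolis sampling at unit temperature with energy E = -eps * C, where C is
// the number of non-bonded nearest-neighbour contacts.  Move set: pivot moves
// (random proper octahedral rotation about a random internal site, applied to
// the shorter arm) mixed with local moves (end rotation, corner flip,
// crankshaft).  R's RNG is used throughout so runs are reproducible from
// set.seed() on the R side.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

const long long OFF = 1 << 14;           // coordinate offset, |coord| < 16384
const long long MOD = 1LL << 15;

inline long long pack(int x, int y, int z) {
  return ((x + OFF) * MOD + (y + OFF)) * MOD + (z + OFF);
}

struct Rot { int m[3][3]; };

// the 24 proper rotations of the octahedral group (signed permutation
// matrices with determinant +1)
std::vector<Rot> make_rotations() {
  std::vector<Rot> rots;
  int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  for (int p = 0; p < 6; ++p) {
    for (int s = 0; s < 8; ++s) {
      int sg[3] = {(s & 1) ? -1 : 1, (s & 2) ? -1 : 1, (s & 4) ? -1 : 1};
      Rot r;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          r.m[i][j] = (perms[p][j] == i) ? sg[i] : 0;
      // determinant
      int det = r.m[0][0]*(r.m[1][1]*r.m[2][2]-r.m[1][2]*r.m[2][1])
              - r.m[0][1]*(r.m[1][0]*r.m[2][2]-r.m[1][2]*r.m[2][0])
              + r.m[0][2]*(r.m[1][0]*r.m[2][1]-r.m[1][1]*r.m[2][0]);
      if (det == 1) rots.push_back(r);
    }
  }
  return rots;
}

const int NB[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};

struct Chain {
  int N;
  std::vector<int> x, y, z;
  std::unordered_map<long long, int> occ;  // packed coordinate -> monomer index
  long long contacts;

  void rebuild_occ() {
    occ.clear();
    occ.reserve(2 * N);
    for (int i = 0; i < N; ++i) occ[pack(x[i], y[i], z[i])] = i;
  }

  long long count_contacts_full() const {
    long long c = 0;
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < 6; ++k) {
        auto it = occ.find(pack(x[i]+NB[k][0], y[i]+NB[k][1], z[i]+NB[k][2]));
        if (it != occ.end()) {
          int j = it->second;
          if (j > i + 1) ++c;        // each non-bonded pair counted once
        }
      }
    }
    return c;
  }

  // contacts of a single site at (px,py,pz) playing index i, with every
  // monomer outside [lo,hi] (the moved block), bonds excluded
  int site_contacts(int px, int py, int pz, int i, int lo, int hi) const {
    int c = 0;
    for (int k = 0; k < 6; ++k) {
      auto it = occ.find(pack(px+NB[k][0], py+NB[k][1], pz+NB[k][2]));
      if (it != occ.end()) {
        int j = it->second;
        if (j >= lo && j <= hi) continue;
        if (j == i - 1 || j == i + 1) continue;
        ++c;
      }
    }
    return c;
  }

  double rg2() const {
    double mx = 0, my = 0, mz = 0;
    for (int i = 0; i < N; ++i) { mx += x[i]; my += y[i]; mz += z[i]; }
    mx /= N; my /= N; mz /= N;
    double s = 0;
    for (int i = 0; i < N; ++i) {
      double dx = x[i] - mx, dy = y[i] - my, dz = z[i] - mz;
      s += dx*dx + dy*dy + dz*dz;
    }
    return s / N;
  }
};

inline int runif_int(int n) {  // uniform on 0..n-1
  int v;
  do { v = (int)std::floor(unif_rand() * n); } while (v >= n);
  return v;
}

// rotate v by 90*q degrees about +axis (0,1,2)
inline void rot_about_axis(int axis, int q, int &vx, int &vy, int &vz) {
  for (int t = 0; t < q; ++t) {
    int nx = vx, ny = vy, nz = vz;
    if (axis == 0)      { ny = -vz; nz =  vy; }
    else if (axis == 1) { nx =  vz; nz = -vx; }
    else                { nx = -vy; ny =  vx; }
    vx = nx; vy = ny; vz = nz;
  }
}

} // namespace

// [[Rcpp::export]]
List isaw_run_cpp(int N, double eps, int n_samples, int sweeps_per_sample,
                  int burnin_sweeps, double p_pivot,
                  Rcpp::Nullable<IntegerMatrix> init_coords,
                  bool audit) {
  if (N < 2) stop("N must be >= 2");
  if (eps < 0) stop("eps must be >= 0");

  static std::vector<Rot> rots = make_rotations();

  Chain ch;
  ch.N = N;
  ch.x.resize(N); ch.y.resize(N); ch.z.resize(N);
  if (init_coords.isNotNull()) {
    IntegerMatrix ic(init_coords);
    if (ic.nrow() != N || ic.ncol() != 3) stop("init coords must be N x 3");
    for (int i = 0; i < N; ++i) { ch.x[i] = ic(i,0); ch.y[i] = ic(i,1); ch.z[i] = ic(i,2); }
  } else {
    for (int i = 0; i < N; ++i) { ch.x[i] = i; ch.y[i] = 0; ch.z[i] = 0; }
  }
  ch.rebuild_occ();
  if ((int)ch.occ.size() != N) stop("initial configuration is not self-avoiding");
  for (int i = 0; i + 1 < N; ++i) {
    int d = std::abs(ch.x[i]-ch.x[i+1]) + std::abs(ch.y[i]-ch.y[i+1]) + std::abs(ch.z[i]-ch.z[i+1]);
    if (d != 1) stop("initial configuration is not connected");
  }
  ch.contacts = ch.count_contacts_full();

  long long total_sweeps = (long long)burnin_sweeps + (long long)n_samples * sweeps_per_sample;
  long long attempted = 0, accepted = 0, accepted_since_audit = 0;
  NumericVector rg2_out(n_samples);
  int sample_idx = 0;

  std::vector<int> nx, ny, nz;  // pivot proposal buffer
  nx.reserve(N); ny.reserve(N); nz.reserve(N);

  for (long long sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int mv = 0; mv < N; ++mv) {
      ++attempted;
      bool acc = false;
      if (N > 3 && unif_rand() < p_pivot) {
        // ---- pivot ----
        int p = 1 + runif_int(N - 2);
        const Rot &R = rots[runif_int((int)rots.size())];
        int lo, hi;
        if (p < N - 1 - p) { lo = 0; hi = p - 1; } else { lo = p + 1; hi = N - 1; }
        int len = hi - lo + 1;
        nx.assign(len, 0); ny.assign(len, 0); nz.assign(len, 0);
        bool ok = true;
        for (int k = lo; k <= hi; ++k) {
          int vx = ch.x[k] - ch.x[p], vy = ch.y[k] - ch.y[p], vz = ch.z[k] - ch.z[p];
          int px = ch.x[p] + R.m[0][0]*vx + R.m[0][1]*vy + R.m[0][2]*vz;
          int py = ch.y[p] + R.m[1][0]*vx + R.m[1][1]*vy + R.m[1][2]*vz;
          int pz = ch.z[p] + R.m[2][0]*vx + R.m[2][1]*vy + R.m[2][2]*vz;
          auto it = ch.occ.find(pack(px, py, pz));
          if (it != ch.occ.end() && (it->second < lo || it->second > hi)) { ok = false; break; }
          nx[k-lo] = px; ny[k-lo] = py; nz[k-lo] = pz;
        }
        if (ok) {
          long long before = 0, after = 0;
          for (int k = lo; k <= hi; ++k)
            before += ch.site_contacts(ch.x[k], ch.y[k], ch.z[k], k, lo, hi);
          for (int k = lo; k <= hi; ++k)
            after += ch.site_contacts(nx[k-lo], ny[k-lo], nz[k-lo], k, lo, hi);
          long long dC = after - before;
          if (dC >= 0 || unif_rand() < std::exp(eps * dC)) {
            for (int k = lo; k <= hi; ++k) ch.occ.erase(pack(ch.x[k], ch.y[k], ch.z[k]));
            for (int k = lo; k <= hi; ++k) {
              ch.x[k] = nx[k-lo]; ch.y[k] = ny[k-lo]; ch.z[k] = nz[k-lo];
              ch.occ[pack(ch.x[k], ch.y[k], ch.z[k])] = k;
            }
            ch.contacts += dC;
            acc = true;
          }
        }
      } else {
        // ---- local move ----
        int i = runif_int(N);
        if (i == 0 || i == N - 1) {
          // end rotation: reattach the end to a random neighbour of its anchor
          int a = (i == 0) ? 1 : N - 2;
          int k = runif_int(6);
          int px = ch.x[a] + NB[k][0], py = ch.y[a] + NB[k][1], pz = ch.z[a] + NB[k][2];
          auto it = ch.occ.find(pack(px, py, pz));
          bool free_site = (it == ch.occ.end()) || (it->second == i);
          if (free_site) {
            int before = ch.site_contacts(ch.x[i], ch.y[i], ch.z[i], i, i, i);
            int after  = ch.site_contacts(px, py, pz, i, i, i);
            int dC = after - before;
            if (dC >= 0 || unif_rand() < std::exp(eps * dC)) {
              ch.occ.erase(pack(ch.x[i], ch.y[i], ch.z[i]));
              ch.x[i] = px; ch.y[i] = py; ch.z[i] = pz;
              ch.occ[pack(px, py, pz)] = i;
              ch.contacts += dC;
              acc = true;
            }
          }
        } else if (unif_rand() < 0.5 || N < 5) {
          // corner (kink) flip
          int dx = ch.x[i+1] - ch.x[i-1], dy = ch.y[i+1] - ch.y[i-1], dz = ch.z[i+1] - ch.z[i-1];
          if (std::abs(dx) + std::abs(dy) + std::abs(dz) == 2) {
            int px = ch.x[i-1] + ch.x[i+1] - ch.x[i];
            int py = ch.y[i-1] + ch.y[i+1] - ch.y[i];
            int pz = ch.z[i-1] + ch.z[i+1] - ch.z[i];
            auto it = ch.occ.find(pack(px, py, pz));
            bool free_site = (it == ch.occ.end()) || (it->second == i);
            if (free_site && !(px == ch.x[i] && py == ch.y[i] && pz == ch.z[i])) {
              int before = ch.site_contacts(ch.x[i], ch.y[i], ch.z[i], i, i, i);
              int after  = ch.site_contacts(px, py, pz, i, i, i);
              int dC = after - before;
              if (dC >= 0 || unif_rand() < std::exp(eps * dC)) {
                ch.occ.erase(pack(ch.x[i], ch.y[i], ch.z[i]));
                ch.x[i] = px; ch.y[i] = py; ch.z[i] = pz;
                ch.occ[pack(px, py, pz)] = i;
                ch.contacts += dC;
                acc = true;
              }
            }
          }
        } else {
          // crankshaft: rotate the two middle sites of a U about the axis
          // joining sites j and j+3 when those are lattice neighbours
          int j = runif_int(N - 3);
          int ax = ch.x[j+3] - ch.x[j], ay = ch.y[j+3] - ch.y[j], az = ch.z[j+3] - ch.z[j];
          if (std::abs(ax) + std::abs(ay) + std::abs(az) == 1) {
            int axis = (ax != 0) ? 0 : (ay != 0 ? 1 : 2);
            int sgn = ax + ay + az;
            int q = 1 + runif_int(3);            // 90, 180 or 270 degrees
            if (sgn < 0) q = 4 - q;              // rotate about the +axis consistently
            int pX[2], pY[2], pZ[2];
            bool ok = true;
            for (int t = 0; t < 2; ++t) {
              int vx = ch.x[j+1+t] - ch.x[j], vy = ch.y[j+1+t] - ch.y[j], vz = ch.z[j+1+t] - ch.z[j];
              rot_about_axis(axis, q, vx, vy, vz);
              pX[t] = ch.x[j] + vx; pY[t] = ch.y[j] + vy; pZ[t] = ch.z[j] + vz;
              auto it = ch.occ.find(pack(pX[t], pY[t], pZ[t]));
              if (it != ch.occ.end() && it->second != j+1 && it->second != j+2) { ok = false; break; }
            }
            if (ok && !(pX[0] == ch.x[j+1] && pY[0] == ch.y[j+1] && pZ[0] == ch.z[j+1])) {
              int before = 0, after = 0;
              for (int t = 0; t < 2; ++t)
                before += ch.site_contacts(ch.x[j+1+t], ch.y[j+1+t], ch.z[j+1+t], j+1+t, j+1, j+2);
              for (int t = 0; t < 2; ++t)
                after += ch.site_contacts(pX[t], pY[t], pZ[t], j+1+t, j+1, j+2);
              int dC = after - before;
              if (dC >= 0 || unif_rand() < std::exp(eps * dC)) {
                for (int t = 0; t < 2; ++t) ch.occ.erase(pack(ch.x[j+1+t], ch.y[j+1+t], ch.z[j+1+t]));
                for (int t = 0; t < 2; ++t) {
                  ch.x[j+1+t] = pX[t]; ch.y[j+1+t] = pY[t]; ch.z[j+1+t] = pZ[t];
                  ch.occ[pack(pX[t], pY[t], pZ[t])] = j+1+t;
                }
                ch.contacts += dC;
                acc = true;
              }
            }
          }
        }
      }
      if (acc) {
        ++accepted;
        if (audit && ++accepted_since_audit >= 1000) {
          accepted_since_audit = 0;
          if (ch.count_contacts_full() != ch.contacts)
            stop("energy bookkeeping mismatch: incremental contact count diverged");
        }
      }
    }
    if (sweep >= burnin_sweeps) {
      long long k = sweep - burnin_sweeps + 1;
      if (k % sweeps_per_sample == 0 && sample_idx < n_samples)
        rg2_out[sample_idx++] = ch.rg2();
    }
    if ((sweep & 255) == 0) Rcpp::checkUserInterrupt();
  }

  if (audit && ch.count_contacts_full() != ch.contacts)
    stop("energy bookkeeping mismatch at end of run");

  IntegerMatrix final_coords(N, 3);
  for (int i = 0; i < N; ++i) {
    final_coords(i,0) = ch.x[i]; final_coords(i,1) = ch.y[i]; final_coords(i,2) = ch.z[i];
  }
  return List::create(
    _["rg2"] = rg2_out,
    _["final_coords"] = final_coords,
    _["acceptance"] = (double)accepted / (double)attempted,
    _["contacts_final"] = (double)ch.contacts
  );
}
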