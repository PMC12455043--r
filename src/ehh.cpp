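// Extended haplotype homozygosity decay and integrated EHH (iHH).
//
// EHH at site s for a carrier set C is the probability that two distinct
// haplotypes drawn from C are identical at every site from the core to s
// (inclusive). iHH is the trapezoid area under the EHH decay curve over
// physical position, truncated by linear interpolation at the point where
// the curve crosses the cutoff. Carriers are tracked as groups of
// identical-so-far haplotypes and refined one site at a time.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct DecayState {
  // Only members of groups of size >= 2 are tracked: a singleton can never
  // again contribute a homozygous pair, so it is dropped as soon as its
  // group shatters. This keeps the per-site cost proportional to the
  // surviving (still-homozygous) carriers.
  std::vector<int> active;  // row indices still in multi-member groups
  std::vector<int> grp;     // group id per active member
  std::vector<int> remap, size;  // reusable buffers
  int n_groups;
  double denom;             // C(n,2) over the full carrier set
  double last_ehh;          // EHH after the previous split

  explicit DecayState(const std::vector<int>& rows)
      : active(rows), grp(rows.size(), 0), n_groups(1),
        denom(rows.size() * (rows.size() - 1) / 2.0), last_ehh(1.0) {}

  // Split groups by allele at one site; returns current EHH.
  double split(const IntegerMatrix& hap, int site) {
    // fast path: if every group is allele-homogeneous at this site the
    // partition (and hence EHH) is unchanged -- the common case during
    // long identical-haplotype stretches
    remap.assign(n_groups, -1);  // first-seen allele per group
    bool shattered = false;
    for (size_t i = 0; i < active.size(); ++i) {
      int a = hap(active[i], site);
      int& seen = remap[grp[i]];
      if (seen < 0) seen = a;
      else if (seen != a) { shattered = true; break; }
    }
    if (!shattered) return last_ehh;
    remap.assign(2 * n_groups, -1);
    int next_id = 0;
    for (size_t i = 0; i < active.size(); ++i) {
      int key = 2 * grp[i] + hap(active[i], site);
      if (remap[key] < 0) remap[key] = next_id++;
      grp[i] = remap[key];
    }
    n_groups = next_id;
    size.assign(n_groups, 0);
    for (size_t i = 0; i < active.size(); ++i) size[grp[i]]++;
    double hom = 0.0;
    for (int g = 0; g < n_groups; ++g) hom += size[g] * (size[g] - 1) / 2.0;
    // compact: drop singletons, renumber surviving groups
    remap.assign(n_groups, -1);
    int keep_id = 0;
    size_t w = 0;
    for (size_t i = 0; i < active.size(); ++i) {
      if (size[grp[i]] < 2) continue;
      if (remap[grp[i]] < 0) remap[grp[i]] = keep_id++;
      active[w] = active[i];
      grp[w] = remap[grp[i]];
      ++w;
    }
    active.resize(w);
    grp.resize(w);
    n_groups = keep_id;
    last_ehh = hom / denom;
    return last_ehh;
  }
};

// One-sided EHH decay curve from a core. dir = +1 (right) or -1 (left).
// When pooled is true the core site itself also partitions haplotypes
// (both-allele EHH); the curve value at the core is 1 by definition either
// way. Appends (position, ehh) points; sets gap_hit when an inter-site gap
// exceeds gap_limit.
void decay_side(const IntegerMatrix& hap, const NumericVector& pos,
                const std::vector<int>& rows, int core, int dir,
                double cutoff, double gap_limit, double max_extend,
                bool pooled, std::vector<double>& xs,
                std::vector<double>& es, bool& gap_hit) {
  DecayState st(rows);
  xs.push_back(pos[core]);
  es.push_back(1.0);
  if (pooled) {
    double e0 = st.split(hap, core);
    if (e0 < cutoff) {  // heterozygous core shatters everything at once
      xs.push_back(pos[core]);
      es.push_back(e0);
      return;
    }
  }
  int m = hap.ncol();
  double prev_pos = pos[core];
  for (int j = core + dir; j >= 0 && j < m; j += dir) {
    if (std::abs(pos[j] - prev_pos) > gap_limit) { gap_hit = true; return; }
    if (std::abs(pos[j] - pos[core]) > max_extend) return;
    if (st.active.empty()) {  // no surviving pairs: EHH is 0 from here on
      xs.push_back(pos[j]);
      es.push_back(0.0);
      return;
    }
    double e = st.split(hap, j);
    xs.push_back(pos[j]);
    es.push_back(e);
    prev_pos = pos[j];
    if (e < cutoff) return;
  }
}

// Streaming one-sided iHH: the trapezoid area is accumulated during the
// decay itself (no curve storage), truncated at the cutoff crossing.
double ihh_side(const IntegerMatrix& hap, const NumericVector& pos,
                const std::vector<int>& rows, int core, int dir,
                double cutoff, double gap_limit, double max_extend,
                bool pooled, bool& gap_hit) {
  DecayState st(rows);
  double e_prev = 1.0;
  if (pooled) {
    double e0 = st.split(hap, core);
    if (e0 < cutoff) return 0.0;
    e_prev = e0;  // zero-width step from 1 to core homozygosity
  }
  int m = hap.ncol();
  double prev_pos = pos[core], area = 0.0;
  for (int j = core + dir; j >= 0 && j < m; j += dir) {
    if (std::abs(pos[j] - prev_pos) > gap_limit) { gap_hit = true; break; }
    if (std::abs(pos[j] - pos[core]) > max_extend) break;
    double e = st.active.empty() ? 0.0 : st.split(hap, j);
    double dx = std::abs(pos[j] - prev_pos);
    if (e < cutoff) {
      if (e_prev > cutoff) {
        double frac = (e_prev - cutoff) / (e_prev - e);
        area += 0.5 * (e_prev + cutoff) * dx * frac;
      }
      return area;
    }
    area += 0.5 * (e + e_prev) * dx;
    e_prev = e;
    prev_pos = pos[j];
  }
  return area;
}

// Two-sided iHH for a carrier set; NA when <2 carriers or a gap is hit.
double ihh_core(const IntegerMatrix& hap, const NumericVector& pos,
                const std::vector<int>& rows, int core, double cutoff,
                double gap_limit, double max_extend, bool pooled) {
  if (rows.size() < 2) return NA_REAL;
  double total = 0.0;
  for (int dir = -1; dir <= 1; dir += 2) {
    bool gap_hit = false;
    total += ihh_side(hap, pos, rows, core, dir, cutoff, gap_limit,
                      max_extend, pooled, gap_hit);
    if (gap_hit) return NA_REAL;
  }
  return total;
}

std::vector<int> all_rows(int n) {
  std::vector<int> rows(n);
  for (int i = 0; i < n; ++i) rows[i] = i;
  return rows;
}

}  // namespace

// [[Rcpp::export(name = ".ehh_curve_cpp")]]
List ehh_curve_cpp(IntegerMatrix hap, NumericVector pos, int core,
                   IntegerVector carriers, int dir, double cutoff,
                   double gap_limit, double max_extend, bool pooled) {
  std::vector<int> rows(carriers.begin(), carriers.end());
  std::vector<double> xs, es;
  bool gap_hit = false;
  decay_side(hap, pos, rows, core, dir, cutoff, gap_limit, max_extend,
             pooled, xs, es, gap_hit);
  return List::create(_["pos"] = NumericVector(xs.begin(), xs.end()),
                      _["ehh"] = NumericVector(es.begin(), es.end()),
                      _["gap_hit"] = gap_hit);
}

// [[Rcpp::export(name = ".ihh_pair_scan_cpp")]]
NumericMatrix ihh_pair_scan_cpp(IntegerMatrix hap, NumericVector pos,
                                IntegerVector anc_allele, IntegerVector cores,
                                double cutoff, double gap_limit,
                                double max_extend) {
  // For each requested core: iHH over ancestral-allele carriers and over
  // derived-allele carriers. Columns: ihh_anc, ihh_der.
  int n = hap.nrow();
  NumericMatrix out(cores.size(), 2);
  for (int c = 0; c < cores.size(); ++c) {
    int j = cores[c];
    std::vector<int> anc_rows, der_rows;
    for (int i = 0; i < n; ++i) {
      if (hap(i, j) == anc_allele[j]) anc_rows.push_back(i);
      else der_rows.push_back(i);
    }
    out(c, 0) = ihh_core(hap, pos, anc_rows, j, cutoff, gap_limit,
                         max_extend, false);
    out(c, 1) = ihh_core(hap, pos, der_rows, j, cutoff, gap_limit,
                         max_extend, false);
  }
  return out;
}

// [[Rcpp::export(name = ".ihh_pooled_scan_cpp")]]
NumericVector ihh_pooled_scan_cpp(IntegerMatrix hap, NumericVector pos,
                                  IntegerVector cores, double cutoff,
                                  double gap_limit, double max_extend) {
  // Pooled (both-allele) iHH per core over all haplotypes of one panel.
  std::vector<int> rows = all_rows(hap.nrow());
  NumericVector out(cores.size());
  for (int c = 0; c < cores.size(); ++c) {
    out[c] = ihh_core(hap, pos, rows, cores[c], cutoff, gap_limit,
                      max_extend, true);
  }
  return out;
}
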