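#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Chromosomes are mosaics of founder-haplotype chunks.  A chunk is a pair
// (start position, founder id); it covers the half-open interval from its
// own start to the next chunk's start (or the chromosome end).  Positions
// are 0-based integer bp, strictly increasing, first chunk at 0; adjacent
// chunks carry distinct ids after normalization.
//
// All randomness goes through R's RNG (unif_rand / R::rpois), so results
// are reproducible from set.seed() and the documented draw order.

// index of the chunk covering position p: largest i with pos[i] <= p
static inline int chunk_index_at(const int *pos, int n, int p) {
  int lo = 0, hi = n - 1;
  while (lo < hi) {
    int mid = lo + (hi - lo + 1) / 2;
    if (pos[mid] <= p) lo = mid; else hi = mid - 1;
  }
  return lo;
}

// append a chunk, merging with the previous one when ids are equal;
// `base` marks where the current chromosome copy starts in the shared
// output buffers so merging never crosses copy boundaries
static inline void append_chunk(std::vector<int> &P, std::vector<int> &I,
                                size_t base, int p, int id) {
  if (I.size() > base && I.back() == id) return;
  P.push_back(p);
  I.push_back(id);
}

// Splice two chromosome copies at the given crossover positions (sorted,
// unique, interior).  The result reads from the starting copy on [0, x1),
// the other on [x1, x2), alternating; output is normalized.
static void splice_copies(const int *apos, const int *aid, int na,
                          const int *bpos, const int *bid, int nb,
                          const int *xo, int nxo, bool start_with_a, int len,
                          std::vector<int> &out_pos, std::vector<int> &out_id) {
  bool use_a = start_with_a;
  int seg_start = 0;
  size_t base = out_pos.size();
  for (int s = 0; s <= nxo; ++s) {
    int seg_end = (s < nxo) ? xo[s] : len;
    const int *pos = use_a ? apos : bpos;
    const int *id = use_a ? aid : bid;
    int n = use_a ? na : nb;
    int i = chunk_index_at(pos, n, seg_start);
    append_chunk(out_pos, out_id, base, seg_start, id[i]);
    for (++i; i < n && pos[i] < seg_end; ++i)
      append_chunk(out_pos, out_id, base, pos[i], id[i]);
    seg_start = seg_end;
    use_a = !use_a;
  }
}

// [[Rcpp::export]]
List cpp_recombine(IntegerVector apos, IntegerVector aid,
                   IntegerVector bpos, IntegerVector bid,
                   int len, IntegerVector crossovers, bool start_with_a) {
  std::vector<int> out_pos, out_id;
  out_pos.reserve(apos.size() + bpos.size() + crossovers.size());
  out_id.reserve(out_pos.capacity());
  splice_copies(apos.begin(), aid.begin(), apos.size(),
                bpos.begin(), bid.begin(), bpos.size(),
                crossovers.begin(), crossovers.size(), start_with_a, len,
                out_pos, out_id);
  return List::create(_["pos"] = wrap(out_pos), _["id"] = wrap(out_id));
}

// Sample crossover bp positions for one meiosis from a cumulative genetic
// map: count ~ Poisson(total Morgans), genetic positions i.i.d. uniform on
// [0, total], inverted to bp by linear interpolation, rounded to integer
// bp; endpoint hits and duplicates removed; returned sorted.
static void sample_xo(const double *bp, const double *cumM, int m, int len,
                      std::vector<int> &out) {
  out.clear();
  double total = cumM[m - 1];
  if (total <= 0) return;
  int k = (int)R::rpois(total);
  if (k == 0) return;
  std::vector<double> g(k);
  for (int i = 0; i < k; ++i) g[i] = unif_rand() * total;
  for (int i = 0; i < k; ++i) {
    // interval j with cumM[j] <= g[i] <= cumM[j+1], skipping flat intervals
    int j = int(std::upper_bound(cumM, cumM + m, g[i]) - cumM) - 1;
    if (j < 0) j = 0;
    if (j >= m - 1) j = m - 2;
    double dM = cumM[j + 1] - cumM[j];
    double x = (dM > 0) ? bp[j] + (g[i] - cumM[j]) / dM * (bp[j + 1] - bp[j])
                        : bp[j];
    int p = (int)std::lround(x);
    if (p >= 1 && p <= len - 1) out.push_back(p);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

// [[Rcpp::export]]
IntegerVector cpp_sample_crossovers(NumericVector bp, NumericVector cumM,
                                    int len) {
  std::vector<int> out;
  sample_xo(bp.begin(), cumM.begin(), bp.size(), len, out);
  return wrap(out);
}

// Flat population layout, per chromosome pair: concatenated chunk arrays
// `pos` and `id` plus `nch`, the chunk count of each chromosome copy.
// Copy 2*i + c (c in {0,1}) is the c-th copy of individual i.

struct FlatPair {
  const int *pos;
  const int *id;
  const int *nch;
  std::vector<int> offset; // start of each copy's chunks
  int ncopy;
};

static FlatPair flatten(List pair_data) {
  FlatPair fp;
  IntegerVector pos = pair_data["pos"], id = pair_data["id"],
                nch = pair_data["nch"];
  fp.pos = pos.begin();
  fp.id = id.begin();
  fp.nch = nch.begin();
  fp.ncopy = nch.size();
  fp.offset.resize(fp.ncopy + 1);
  fp.offset[0] = 0;
  for (int j = 0; j < fp.ncopy; ++j) fp.offset[j + 1] = fp.offset[j] + nch[j];
  return fp;
}

// One Wright-Fisher reproduction step for a batch of offspring.
// `parents` is a 2 x n matrix of 0-based individual indices into the flat
// parental structure.  Draw order (fixed contract): offspring-major, then
// parent slot 0/1, then chromosome pair; per gamete: crossovers, then a
// fair coin for the starting copy.
// [[Rcpp::export]]
List cpp_make_children(List chrom, IntegerVector lengths,
                       IntegerMatrix parents, List maps) {
  int npair = chrom.size();
  int noff = parents.ncol();
  std::vector<FlatPair> fps;
  fps.reserve(npair);
  for (int k = 0; k < npair; ++k) fps.push_back(flatten(chrom[k]));

  std::vector<const double *> map_bp(npair), map_cum(npair);
  std::vector<int> map_m(npair);
  for (int k = 0; k < npair; ++k) {
    List mk = maps[k];
    NumericVector bp = mk["bp"], cum = mk["cum"];
    map_bp[k] = bp.begin();
    map_cum[k] = cum.begin();
    map_m[k] = bp.size();
  }

  std::vector<std::vector<int>> out_pos(npair), out_id(npair), out_nch(npair);
  for (int k = 0; k < npair; ++k) {
    out_pos[k].reserve(fps[k].offset[fps[k].ncopy]);
    out_id[k].reserve(fps[k].offset[fps[k].ncopy]);
    out_nch[k].reserve(2 * noff);
  }

  std::vector<int> xo;
  for (int o = 0; o < noff; ++o) {
    for (int slot = 0; slot < 2; ++slot) {
      int par = parents(slot, o);
      for (int k = 0; k < npair; ++k) {
        FlatPair &fp = fps[k];
        sample_xo(map_bp[k], map_cum[k], map_m[k], lengths[k], xo);
        bool start_a = unif_rand() < 0.5;
        int c0 = 2 * par, c1 = 2 * par + 1;
        size_t before = out_pos[k].size();
        splice_copies(fp.pos + fp.offset[c0], fp.id + fp.offset[c0],
                      fp.nch[c0],
                      fp.pos + fp.offset[c1], fp.id + fp.offset[c1],
                      fp.nch[c1], xo.data(), xo.size(), start_a, lengths[k],
                      out_pos[k], out_id[k]);
        out_nch[k].push_back((int)(out_pos[k].size() - before));
      }
    }
  }

  List res(npair);
  for (int k = 0; k < npair; ++k)
    res[k] = List::create(_["pos"] = wrap(out_pos[k]),
                          _["id"] = wrap(out_id[k]),
                          _["nch"] = wrap(out_nch[k]));
  return res;
}

// Founder id carried by every chromosome copy at each query position.
// Returns an ncopy x nquery integer matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_founder_ids_at(IntegerVector pos, IntegerVector id,
                                 IntegerVector nch, IntegerVector query) {
  int ncopy = nch.size(), nq = query.size();
  IntegerMatrix out(ncopy, nq);
  int off = 0;
  for (int j = 0; j < ncopy; ++j) {
    const int *p = pos.begin() + off;
    const int *i = id.begin() + off;
    int n = nch[j];
    for (int q = 0; q < nq; ++q)
      out(j, q) = i[chunk_index_at(p, n, query[q])];
    off += n;
  }
  return out;
}
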