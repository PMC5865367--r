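// Gene-drop engine: meiosis with Poisson-distributed crossovers (Haldane, no
// interference), recurrent symmetric allele-flip mutation, and whole-population
// random-mating loops. Haplotypes are stored as one row per gamete (individual
// i occupies rows 2i and 2i+1, 0-based), loci sorted by (chromosome, position).
//
// All randomness comes from R's RNG so results are reproducible via set.seed().

#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

namespace {

struct MapInfo {
  int n_loci;
  int n_chrom;
  std::vector<int> start;        // first locus index of chromosome c
  std::vector<int> end;          // one-past-last locus index
  std::vector<double> len;       // chromosome length in Morgans
  const double* pos;             // per-locus position in Morgans
};

MapInfo make_map(const IntegerVector& chrom_start, const IntegerVector& chrom_end,
                 const NumericVector& chrom_len, const NumericVector& pos) {
  MapInfo m;
  m.n_chrom = chrom_start.size();
  m.n_loci = pos.size();
  m.start.assign(chrom_start.begin(), chrom_start.end());
  m.end.assign(chrom_end.begin(), chrom_end.end());
  m.len.assign(chrom_len.begin(), chrom_len.end());
  m.pos = REAL(pos);
  return m;
}

// Form one gamete from a parent's two haplotypes h1/h2 into g.
inline void make_gamete(const uint8_t* h1, const uint8_t* h2, uint8_t* g,
                        const MapInfo& m, std::vector<double>& cxbuf) {
  for (int c = 0; c < m.n_chrom; ++c) {
    const int s = m.start[c], e = m.end[c];
    int cur = (unif_rand() < 0.5) ? 1 : 0;   // which haplotype we copy from
    const int ncx = (int) R::rpois(m.len[c]);
    if (ncx == 0) {
      std::memcpy(g + s, (cur ? h2 : h1) + s, (size_t)(e - s));
      continue;
    }
    cxbuf.resize(ncx);
    for (int k = 0; k < ncx; ++k) cxbuf[k] = unif_rand() * m.len[c];
    std::sort(cxbuf.begin(), cxbuf.end());
    int i = s;
    for (int k = 0; k <= ncx; ++k) {
      int j;
      if (k == ncx) {
        j = e;
      } else {
        j = (int)(std::lower_bound(m.pos + i, m.pos + e, cxbuf[k]) - m.pos);
      }
      if (j > i) std::memcpy(g + i, (cur ? h2 : h1) + i, (size_t)(j - i));
      i = j;
      cur = 1 - cur;
    }
  }
}

// Symmetric allele-flip mutation: each locus mutates with probability mu.
inline void mutate_gamete(uint8_t* g, int n_loci, double mu) {
  if (mu <= 0) return;
  const int nmut = (int) R::rbinom((double) n_loci, mu);
  for (int k = 0; k < nmut; ++k) {
    const int j = (int) (unif_rand() * n_loci);
    if (j < n_loci) g[j] = 1 - g[j];
  }
}

std::vector<uint8_t> to_bytes(const IntegerMatrix& haps) {
  const int nr = haps.nrow(), nc = haps.ncol();
  std::vector<uint8_t> out((size_t) nr * nc);
  for (int j = 0; j < nc; ++j) {
    const int* col = &haps(0, j);
    for (int i = 0; i < nr; ++i) out[(size_t) i * nc + j] = (uint8_t) col[i];
  }
  return out;
}

IntegerMatrix from_bytes(const std::vector<uint8_t>& buf, int nr, int nc) {
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    int* col = &out(0, j);
    for (int i = 0; i < nr; ++i) col[i] = buf[(size_t) i * nc + j];
  }
  return out;
}

} // namespace

// Random mating of a sexed population for n_generations at constant size.
// Individuals 0..n/2-1 are male, the rest female, in every generation.
// Returns the final generation's haplotypes (2n x L).
// [[Rcpp::export]]
IntegerMatrix cpp_random_mate_generations(IntegerMatrix haps, int n_generations,
                                          IntegerVector chrom_start, IntegerVector chrom_end,
                                          NumericVector chrom_len, NumericVector pos,
                                          double mutation_rate) {
  const MapInfo m = make_map(chrom_start, chrom_end, chrom_len, pos);
  const int L = haps.ncol();
  const int n_ind = haps.nrow() / 2;
  if (2 * n_ind != haps.nrow()) stop("haplotype matrix must have an even number of rows");
  if (n_ind < 2) stop("need at least 2 individuals");
  const int n_male = n_ind / 2;
  const int n_female = n_ind - n_male;
  if (n_male < 1 || n_female < 1) stop("need at least one male and one female");

  std::vector<uint8_t> cur = to_bytes(haps);
  std::vector<uint8_t> nxt((size_t) 2 * n_ind * L);
  std::vector<double> cxbuf;

  for (int g = 0; g < n_generations; ++g) {
    for (int i = 0; i < n_ind; ++i) {
      const int sire = (int) (unif_rand() * n_male);
      const int dam  = n_male + (int) (unif_rand() * n_female);
      uint8_t* g1 = &nxt[(size_t) (2 * i) * L];
      uint8_t* g2 = &nxt[(size_t) (2 * i + 1) * L];
      make_gamete(&cur[(size_t) (2 * sire) * L], &cur[(size_t) (2 * sire + 1) * L], g1, m, cxbuf);
      make_gamete(&cur[(size_t) (2 * dam) * L],  &cur[(size_t) (2 * dam + 1) * L],  g2, m, cxbuf);
      mutate_gamete(g1, L, mutation_rate);
      mutate_gamete(g2, L, mutation_rate);
    }
    cur.swap(nxt);
  }
  return from_bytes(cur, 2 * n_ind, L);
}

// Offspring of explicit (sire, dam) pairs. sire/dam are 1-based individual
// indices into `haps`. Offspring k receives its first haplotype from sire[k],
// its second from dam[k]. Returns (2 * n_offspring) x L.
// [[Rcpp::export]]
IntegerMatrix cpp_mate(IntegerMatrix haps, IntegerVector sire, IntegerVector dam,
                       IntegerVector chrom_start, IntegerVector chrom_end,
                       NumericVector chrom_len, NumericVector pos,
                       double mutation_rate) {
  const MapInfo m = make_map(chrom_start, chrom_end, chrom_len, pos);
  const int L = haps.ncol();
  const int n_ind = haps.nrow() / 2;
  const int noff = sire.size();
  if (dam.size() != noff) stop("sire and dam must have equal length");

  std::vector<uint8_t> par = to_bytes(haps);
  std::vector<uint8_t> out((size_t) 2 * noff * L);
  std::vector<double> cxbuf;

  for (int k = 0; k < noff; ++k) {
    const int s = sire[k] - 1, d = dam[k] - 1;
    if (s < 0 || s >= n_ind || d < 0 || d >= n_ind) stop("parent index out of range");
    uint8_t* g1 = &out[(size_t) (2 * k) * L];
    uint8_t* g2 = &out[(size_t) (2 * k + 1) * L];
    make_gamete(&par[(size_t) (2 * s) * L], &par[(size_t) (2 * s + 1) * L], g1, m, cxbuf);
    make_gamete(&par[(size_t) (2 * d) * L], &par[(size_t) (2 * d + 1) * L], g2, m, cxbuf);
    mutate_gamete(g1, L, mutation_rate);
    mutate_gamete(g2, L, mutation_rate);
  }
  return from_bytes(out, 2 * noff, L);
}

// One gamete per requested parent (1-based indices). Returns n x L.
// [[Rcpp::export]]
IntegerMatrix cpp_gametes(IntegerMatrix haps, IntegerVector parent,
                          IntegerVector chrom_start, IntegerVector chrom_end,
                          NumericVector chrom_len, NumericVector pos,
                          double mutation_rate) {
  const MapInfo m = make_map(chrom_start, chrom_end, chrom_len, pos);
  const int L = haps.ncol();
  const int n_ind = haps.nrow() / 2;
  const int n = parent.size();

  std::vector<uint8_t> par = to_bytes(haps);
  std::vector<uint8_t> out((size_t) n * L);
  std::vector<double> cxbuf;

  for (int k = 0; k < n; ++k) {
    const int p = parent[k] - 1;
    if (p < 0 || p >= n_ind) stop("parent index out of range");
    uint8_t* g = &out[(size_t) k * L];
    make_gamete(&par[(size_t) (2 * p) * L], &par[(size_t) (2 * p + 1) * L], g, m, cxbuf);
    mutate_gamete(g, L, mutation_rate);
  }
  return from_bytes(out, n, L);
}
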