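#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Merge one read pair by maximum-agreement overlap scan.
//
// r2 is supplied already reverse-complemented (same strand as r1). For every
// candidate overlap length L in [min_overlap, min(n1, n2)] the suffix of r1
// is compared with the prefix of r2; the L maximizing the number of matching
// bases, subject to mismatches <= max_mismatch_rate * L, wins. Ties go to
// the longer overlap. Consensus takes the higher-quality base at
// disagreements (mate 1 wins quality ties).
//
// Returns per pair: merged sequence, merged quality, overlap length,
// mismatches in overlap (overlap 0 => rejection).
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector r1, CharacterVector r2,
                     CharacterVector q1, CharacterVector q2,
                     int min_overlap, double max_mismatch_rate) {
  int n = r1.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector overlap(n), mismatches(n);
  std::string buf, qbuf;
  for (int i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(r1, i));
    const char *b = CHAR(STRING_ELT(r2, i));
    const char *qa = CHAR(STRING_ELT(q1, i));
    const char *qb = CHAR(STRING_ELT(q2, i));
    int n1 = std::strlen(a), n2 = std::strlen(b);
    int lmax = std::min(n1, n2);
    int best_len = 0, best_matches = -1, best_mm = 0;
    for (int L = lmax; L >= min_overlap; --L) {
      if (L <= best_matches) break;  // cannot beat current best
      int allowed = (int)std::floor(max_mismatch_rate * L);
      int mm = 0;
      const char *sa = a + (n1 - L);
      for (int k = 0; k < L; ++k) {
        if (sa[k] != b[k] && ++mm > allowed) break;
      }
      if (mm > allowed) continue;
      int matches = L - mm;
      if (matches > best_matches) {
        best_matches = matches;
        best_len = L;
        best_mm = mm;
      }
    }
    overlap[i] = best_len;
    mismatches[i] = best_mm;
    if (best_len == 0) {
      mseq[i] = NA_STRING;
      mqual[i] = NA_STRING;
      continue;
    }
    int L = best_len;
    int total = n1 + n2 - L;
    buf.assign(a, n1);
    qbuf.assign(qa, n1);
    buf.resize(total);
    qbuf.resize(total);
    // overlap consensus: positions n1-L .. n1-1 of r1 vs 0 .. L-1 of r2
    for (int k = 0; k < L; ++k) {
      int pa = n1 - L + k;
      if (a[pa] != b[k] && qb[k] > qa[pa]) {
        buf[pa] = b[k];
        qbuf[pa] = qb[k];
      } else if (a[pa] == b[k] && qb[k] > qa[pa]) {
        qbuf[pa] = qb[k];
      }
    }
    for (int k = L; k < n2; ++k) {
      buf[n1 - L + k] = b[k];
      qbuf[n1 - L + k] = qb[k];
    }
    mseq[i] = buf;
    mqual[i] = qbuf;
  }
  return List::create(_["sequence"] = mseq, _["quality"] = mqual,
                      _["overlap"] = overlap, _["mismatches"] = mismatches);
}

// Best Hamming match of each query against a candidate set.
//
// Returns the 1-based index of the unique candidate within max_mm
// mismatches, 0 when none qualifies, and -1 when two candidates tie at the
// minimal qualifying distance (ambiguous). Queries shorter than the
// candidates never match. 'N' (or any non-candidate base) counts as a
// mismatch.
// [[Rcpp::export]]
IntegerVector cpp_hamming_assign(CharacterVector queries,
                                 CharacterVector candidates, int max_mm) {
  int nq = queries.size(), nc = candidates.size();
  std::vector<const char*> cand(nc);
  std::vector<int> clen(nc);
  for (int j = 0; j < nc; ++j) {
    cand[j] = CHAR(STRING_ELT(candidates, j));
    clen[j] = std::strlen(cand[j]);
  }
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    if (STRING_ELT(queries, i) == NA_STRING) { out[i] = 0; continue; }
    const char *q = CHAR(STRING_ELT(queries, i));
    int qlen = std::strlen(q);
    int best = max_mm + 1, best_j = 0, ties = 0;
    for (int j = 0; j < nc; ++j) {
      if (qlen != clen[j]) continue;
      int mm = 0;
      for (int k = 0; k < clen[j]; ++k) {
        if (q[k] != cand[j][k] && ++mm > max_mm) break;
      }
      if (mm > max_mm) continue;
      if (mm < best) { best = mm; best_j = j + 1; ties = 1; }
      else if (mm == best) ++ties;
    }
    out[i] = (best_j == 0) ? 0 : (ties > 1 ? -1 : best_j);
  }
  return out;
}

// Plant i.i.d. substitution errors at the given per-base rate, using R's RNG
// so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector seqs, double rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  RNGScope scope;
  std::string buf;
  for (int i = 0; i < n; ++i) {
    buf = CHAR(STRING_ELT(seqs, i));
    for (size_t k = 0; k < buf.size(); ++k) {
      if (unif_rand() < rate) {
        char c = buf[k], nc = c;
        while (nc == c) nc = bases[(int)(unif_rand() * 4) & 3];
        buf[k] = nc;
      }
    }
    out[i] = buf;
  }
  return out;
}
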