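// Gapless scanning kernels: sliding Hamming matching of tags against
// reference sequences, and position-weighted miRNA/target duplex scoring.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline char canon(char c) {
  switch (c) {
    case 'a': return 'A'; case 'c': return 'C'; case 'g': return 'G';
    case 'u': case 'U': case 't': return 'T';
    default: return (c == 'T') ? 'T' : (char)toupper(c);
  }
}

static std::string canonStr(const std::string& s) {
  std::string out(s);
  for (size_t i = 0; i < out.size(); ++i) out[i] = canon(out[i]);
  return out;
}

// Best (minimum) Hamming distance of `tag` slid along `ref` with full
// overlap, T/U identified. Returns distance and 0-based offset of the best
// window (smallest offset wins ties). Distance -1 when tag longer than ref.
// [[Rcpp::export]]
DataFrame c_match_many(CharacterVector tags, CharacterVector refs, int max_mm) {
  std::vector<std::string> T(tags.size()), R(refs.size());
  for (int i = 0; i < tags.size(); ++i) T[i] = canonStr(as<std::string>(tags[i]));
  for (int i = 0; i < refs.size(); ++i) R[i] = canonStr(as<std::string>(refs[i]));
  std::vector<int> out_tag, out_ref, out_mm, out_off;
  for (int ti = 0; ti < (int)T.size(); ++ti) {
    const std::string& t = T[ti];
    int m = (int)t.size();
    for (int ri = 0; ri < (int)R.size(); ++ri) {
      const std::string& r = R[ri];
      int L = (int)r.size();
      if (m > L || m == 0) continue;
      int best = max_mm + 1, bestOff = -1;
      for (int off = 0; off + m <= L; ++off) {
        int d = 0;
        for (int k = 0; k < m; ++k) {
          if (t[k] != r[off + k]) { if (++d >= best) break; }
        }
        if (d < best) { best = d; bestOff = off; if (best == 0) break; }
      }
      if (bestOff >= 0 && best <= max_mm) {
        out_tag.push_back(ti + 1); out_ref.push_back(ri + 1);
        out_mm.push_back(best); out_off.push_back(bestOff);
      }
    }
  }
  return DataFrame::create(_["tag"] = out_tag, _["ref"] = out_ref,
                           _["mismatches"] = out_mm, _["offset"] = out_off);
}

// pairing classes for the miRNA/target duplex (DNA space, antiparallel):
// 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch
static inline int duplexClass(char mi, char tx) {
  // Watson-Crick: A-T, T-A, G-C, C-G
  if ((mi == 'A' && tx == 'T') || (mi == 'T' && tx == 'A') ||
      (mi == 'G' && tx == 'C') || (mi == 'C' && tx == 'G')) return 0;
  // wobble G:U -> miRNA G vs transcript T, or miRNA T(U) vs transcript G
  if ((mi == 'G' && tx == 'T') || (mi == 'T' && tx == 'G')) return 1;
  return 2;
}

// Exhaustive gapless scan of miRNAs against transcripts with Allen-style
// position-weighted penalties. miRNA position p (1-based, from the 5' end)
// faces transcript base site_start + len - p (site on the sense strand).
// [[Rcpp::export]]
DataFrame c_target_scan(CharacterVector mirnas, CharacterVector transcripts,
                        double max_score, double mm_penalty, double gu_penalty,
                        int seed_from, int seed_to, double seed_mult,
                        int cleave_from, int cleave_to, bool allow_cleavage_mm,
                        bool strict_hamming) {
  std::vector<std::string> M(mirnas.size()), X(transcripts.size());
  for (int i = 0; i < mirnas.size(); ++i) M[i] = canonStr(as<std::string>(mirnas[i]));
  for (int i = 0; i < transcripts.size(); ++i) X[i] = canonStr(as<std::string>(transcripts[i]));
  std::vector<int> o_mi, o_tx, o_start, o_mm, o_gu;
  std::vector<double> o_score;
  for (int mi = 0; mi < (int)M.size(); ++mi) {
    const std::string& m = M[mi];
    int len = (int)m.size();
    if (len == 0) continue;
    for (int xi = 0; xi < (int)X.size(); ++xi) {
      const std::string& x = X[xi];
      int L = (int)x.size();
      if (len > L) continue; // transcript shorter than miRNA: skipped
      for (int s = 0; s + len <= L; ++s) {
        double score = 0.0;
        int nmm = 0, ngu = 0;
        bool cleaveHit = false, bail = false;
        for (int p = 1; p <= len; ++p) {
          int cls = duplexClass(m[p - 1], x[s + len - p]);
          if (cls == 0) continue;
          double pen = (cls == 1 && !strict_hamming) ? gu_penalty : mm_penalty;
          if (p >= seed_from && p <= seed_to) pen *= seed_mult;
          score += pen;
          if (cls == 1) ++ngu; else ++nmm;
          if (cls == 2 && p >= cleave_from && p <= cleave_to) cleaveHit = true;
          if (score > max_score + 1e-9) { bail = true; break; }
        }
        if (bail) continue;
        if (cleaveHit && !allow_cleavage_mm) continue;
        o_mi.push_back(mi + 1); o_tx.push_back(xi + 1); o_start.push_back(s);
        o_mm.push_back(nmm); o_gu.push_back(ngu); o_score.push_back(score);
      }
    }
  }
  return DataFrame::create(_["mirna"] = o_mi, _["transcript"] = o_tx,
                           _["site_start"] = o_start, _["mismatches"] = o_mm,
                           _["gu_wobbles"] = o_gu, _["score"] = o_score);
}
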