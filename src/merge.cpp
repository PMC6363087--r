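#include <Rcpp.h>
using namespace Rcpp;

static inline char comp(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// Merge one read pair by overlap, FLASH-style.
// r2 arrives in sequencer orientation and is reverse-complemented here.
// Candidate overlaps o run from min(len1, len2) down to min_overlap (innie
// orientation only); the first candidate whose mismatch fraction is within
// max_mismatch_frac wins, i.e. the longest admissible overlap.
// Consensus in the overlap: agreeing bases keep max quality; disagreeing
// bases keep the higher-quality base, quality ties keep the r1 base with
// quality min(q1, q2).
static bool merge_one(const std::string& s1, const std::string& q1,
                      const std::string& s2raw, const std::string& q2raw,
                      int min_overlap, double max_mismatch_frac,
                      std::string& out_seq, std::string& out_qual,
                      int& out_overlap, int& out_mismatch) {
  const int l1 = s1.size(), l2 = s2raw.size();
  std::string s2(l2, 'N'), q2(l2, '!');
  for (int i = 0; i < l2; ++i) {
    s2[i] = comp(s2raw[l2 - 1 - i]);
    q2[i] = q2raw[l2 - 1 - i];
  }
  const int omax = std::min(l1, l2);
  for (int o = omax; o >= min_overlap; --o) {
    const int budget = (int)std::floor(max_mismatch_frac * o);
    int mm = 0;
    const int off = l1 - o;
    for (int i = 0; i < o; ++i) {
      if (s1[off + i] != s2[i] && ++mm > budget) break;
    }
    if (mm > budget) continue;
    out_seq.assign(s1, 0, off);
    out_qual.assign(q1, 0, off);
    for (int i = 0; i < o; ++i) {
      const char b1 = s1[off + i], b2 = s2[i];
      const char c1 = q1[off + i], c2 = q2[i];
      if (b1 == b2) {
        out_seq.push_back(b1);
        out_qual.push_back(std::max(c1, c2));
      } else if (c1 > c2) {
        out_seq.push_back(b1);
        out_qual.push_back(c1);
      } else if (c2 > c1) {
        out_seq.push_back(b2);
        out_qual.push_back(c2);
      } else {
        out_seq.push_back(b1);
        out_qual.push_back(std::min(c1, c2));
      }
    }
    out_seq.append(s2, o, l2 - o);
    out_qual.append(q2, o, l2 - o);
    out_overlap = o;
    out_mismatch = mm;
    return true;
  }
  return false;
}

// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double max_mismatch_frac) {
  const int n = seq1.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector ovl(n), mism(n);
  LogicalVector merged(n);
  std::string os, oq;
  for (int i = 0; i < n; ++i) {
    os.clear(); oq.clear();
    int oo = 0, om = 0;
    bool ok = merge_one(as<std::string>(seq1[i]), as<std::string>(qual1[i]),
                        as<std::string>(seq2[i]), as<std::string>(qual2[i]),
                        min_overlap, max_mismatch_frac, os, oq, oo, om);
    merged[i] = ok;
    if (ok) {
      mseq[i] = os; mqual[i] = oq; ovl[i] = oo; mism[i] = om;
    } else {
      mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      ovl[i] = NA_INTEGER; mism[i] = NA_INTEGER;
    }
  }
  return List::create(_["merged"] = merged, _["seq"] = mseq, _["qual"] = mqual,
                      _["overlap"] = ovl, _["mismatches"] = mism);
}
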