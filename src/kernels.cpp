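#include <Rcpp.h>
using namespace Rcpp;

// Base comparison for overlap/primer matching: N never matches anything,
// including another N (conservative).
static inline bool base_mismatch(char a, char b) {
  return a != b || a == 'N' || b == 'N';
}

// Overlap-merge a vector of read pairs. seq2/qual2 must already be
// reverse-complemented / reversed so both mates are forward-oriented.
// Candidate overlap lengths run from min(len1, len2) down to min_overlap;
// the longest overlap whose mismatch fraction is <= max_mismatch_frac wins
// (scanning longest-first makes the selection deterministic). Disagreeing
// overlap bases resolve to the higher-quality base (tie -> read1's base);
// merged quality at each overlap position is the max of the two.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double max_mismatch_frac) {
  int n = seq1.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector olen(n), omis(n);
  LogicalVector merged(n);
  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(seq1[i]);
    std::string q1 = as<std::string>(qual1[i]);
    std::string s2 = as<std::string>(seq2[i]);
    std::string q2 = as<std::string>(qual2[i]);
    int l1 = s1.size(), l2 = s2.size();
    if (l1 == 0 || l2 == 0) stop("empty sequence in read pair %d", i + 1);
    int best_o = -1, best_m = 0;
    int omax = std::min(l1, l2);
    for (int o = omax; o >= min_overlap; --o) {
      int allowed = (int)std::floor(max_mismatch_frac * o + 1e-9);
      int mism = 0;
      bool ok = true;
      for (int j = 0; j < o; ++j) {
        if (base_mismatch(s1[l1 - o + j], s2[j])) {
          if (++mism > allowed) { ok = false; break; }
        }
      }
      if (ok) { best_o = o; best_m = mism; break; }
    }
    if (best_o < 0) {
      merged[i] = false;
      mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      olen[i] = NA_INTEGER; omis[i] = NA_INTEGER;
      continue;
    }
    int o = best_o;
    std::string ms = s1.substr(0, l1 - o);
    std::string mq = q1.substr(0, l1 - o);
    for (int j = 0; j < o; ++j) {
      char a = s1[l1 - o + j], b = s2[j];
      char qa = q1[l1 - o + j], qb = q2[j];
      ms.push_back(qb > qa ? b : a);
      mq.push_back(qa > qb ? qa : qb);
    }
    ms += s2.substr(o);
    mq += q2.substr(o);
    merged[i] = true;
    mseq[i] = ms; mqual[i] = mq;
    olen[i] = o; omis[i] = best_m;
  }
  return List::create(_["merged"] = merged, _["seq"] = mseq,
                      _["qual"] = mqual, _["overlap_len"] = olen,
                      _["overlap_mismatches"] = omis);
}

static inline int hamming_capped(const std::string &s, size_t offset,
                                 const std::string &p, int cap) {
  int d = 0;
  for (size_t j = 0; j < p.size(); ++j) {
    if (base_mismatch(s[offset + j], p[j])) {
      if (++d > cap) return d;
    }
  }
  return d;
}

// Primer demultiplexing of merged reads. rcseqs are the reverse
// complements of seqs; end_seq[a] is the reverse complement of amplicon
// a's reverse primer, i.e. the 3' terminus of the forward-oriented
// amplicon. A candidate (amplicon, orientation) qualifies when both the
// 5' prefix vs forward primer and the 3' suffix vs end_seq are within
// max_diff mismatches each; the candidate minimising total mismatches
// wins. Ties between different amplicons -> ambiguous (status 2); a tie
// between orientations of the same amplicon resolves to forward.
// status: 0 assigned, 1 no qualifying match, 2 ambiguous, 3 read shorter
// than primers for every amplicon.
// [[Rcpp::export]]
List demux_cpp(CharacterVector seqs, CharacterVector rcseqs,
               CharacterVector fwd_primer, CharacterVector end_seq,
               int max_diff) {
  int n = seqs.size(), na = fwd_primer.size();
  std::vector<std::string> pf(na), pe(na);
  for (int a = 0; a < na; ++a) {
    pf[a] = as<std::string>(fwd_primer[a]);
    pe[a] = as<std::string>(end_seq[a]);
  }
  IntegerVector amp(n), strand(n), mism5(n), mism3(n), status(n);
  for (int i = 0; i < n; ++i) {
    std::string fw = as<std::string>(seqs[i]);
    std::string rv = as<std::string>(rcseqs[i]);
    int best_total = INT_MAX, best_a = -1, best_strand = 0;
    int best_d5 = 0, best_d3 = 0;
    bool ambiguous = false, any_long_enough = false;
    for (int a = 0; a < na; ++a) {
      size_t need = pf[a].size() + pe[a].size();
      if (fw.size() < need) continue;
      any_long_enough = true;
      for (int st = 0; st < 2; ++st) {
        const std::string &s = (st == 0) ? fw : rv;
        int d5 = hamming_capped(s, 0, pf[a], max_diff);
        if (d5 > max_diff) continue;
        int d3 = hamming_capped(s, s.size() - pe[a].size(), pe[a], max_diff);
        if (d3 > max_diff) continue;
        int total = d5 + d3;
        if (total < best_total) {
          best_total = total; best_a = a; best_strand = st;
          best_d5 = d5; best_d3 = d3; ambiguous = false;
        } else if (total == best_total && a != best_a) {
          ambiguous = true;
        }
      }
    }
    if (!any_long_enough) {
      amp[i] = 0; strand[i] = NA_INTEGER;
      mism5[i] = NA_INTEGER; mism3[i] = NA_INTEGER; status[i] = 3;
    } else if (best_a < 0) {
      amp[i] = 0; strand[i] = NA_INTEGER;
      mism5[i] = NA_INTEGER; mism3[i] = NA_INTEGER; status[i] = 1;
    } else if (ambiguous) {
      amp[i] = 0; strand[i] = NA_INTEGER;
      mism5[i] = NA_INTEGER; mism3[i] = NA_INTEGER; status[i] = 2;
    } else {
      amp[i] = best_a + 1; strand[i] = best_strand + 1;
      mism5[i] = best_d5; mism3[i] = best_d3; status[i] = 0;
    }
  }
  return List::create(_["amp"] = amp, _["strand"] = strand,
                      _["mism5"] = mism5, _["mism3"] = mism3,
                      _["status"] = status);
}
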