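#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
using namespace Rcpp;

// DNA base comparison: 'N' never matches anything (including itself).
static inline bool base_match(char a, char b) {
  return a == b && a != 'N' && a != 'n';
}

static const int NEG = INT_MIN / 4;

//' @noRd
// [[Rcpp::export(name = ".cpp_sw_scores")]]
IntegerMatrix cpp_sw_scores(CharacterVector reads, CharacterVector refs,
                            int match, int mismatch,
                            int gap_open, int gap_ext) {
  const int nr = reads.size(), nf = refs.size();
  IntegerMatrix out(nr, nf);
  std::vector<std::string> refv(nf);
  for (int k = 0; k < nf; ++k) refv[k] = as<std::string>(refs[k]);
  const int go = gap_open + gap_ext, ge = gap_ext;
  std::vector<int> H, E;
  for (int i = 0; i < nr; ++i) {
    const std::string rd = as<std::string>(reads[i]);
    const char *rp = rd.c_str();
    const int n = rd.size();
    H.assign(n + 1, 0);
    E.assign(n + 1, NEG);
    for (int k = 0; k < nf; ++k) {
      const std::string &rf = refv[k];
      const char *fp = rf.c_str();
      const int m = rf.size();
      std::fill(H.begin(), H.end(), 0);
      std::fill(E.begin(), E.end(), NEG);
      int best = 0;
      for (int a = 0; a < m; ++a) {
        int diag = 0, F = NEG, Hprev = 0;
        const char ca = fp[a];
        int *Hp = H.data(); int *Ep = E.data();
        for (int b = 1; b <= n; ++b) {
          int e = Ep[b] - ge; int eo = Hp[b] - go;
          if (eo > e) e = eo;
          int f = F - ge; int fo = Hprev - go;
          if (fo > f) f = fo;
          int h = diag + (base_match(ca, rp[b - 1]) ? match : mismatch);
          if (e > h) h = e;
          if (f > h) h = f;
          if (h < 0) h = 0;
          diag = Hp[b];
          Hp[b] = h; Ep[b] = e; F = f; Hprev = h;
          if (h > best) best = h;
        }
      }
      out(i, k) = best;
    }
    if (i % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// End-free ("overlap") global alignment of one reference against one read,
// with traceback, greedy matched extension toward the junction, and mapping
// of a reference anchor position onto the read.
//
// extend_right = true  : V side, extension proceeds 3' (rightwards)
// extend_right = false : J side, extension proceeds 5' (leftwards)
// All returned coordinates are 1-based inclusive; anchor_read is NA when the
// anchor is not covered by the (extended) alignment.
//' @noRd
// [[Rcpp::export(name = ".cpp_overlap_align")]]
DataFrame cpp_overlap_align(CharacterVector reads, CharacterVector refs,
                            IntegerVector ref_idx, IntegerVector anchor_pos,
                            bool extend_right,
                            int match, int mismatch,
                            int gap_open, int gap_ext) {
  const int nr = reads.size();
  const int nf = refs.size();
  std::vector<std::string> refv(nf);
  for (int k = 0; k < nf; ++k) refv[k] = as<std::string>(refs[k]);
  const int go = gap_open + gap_ext, ge = gap_ext;

  IntegerVector score(nr);
  IntegerVector read_start(nr), read_end(nr), ref_start(nr), ref_end(nr),
      matches(nr), aln_len(nr), anchor_read(nr);
  std::vector<int> H, F;
  std::vector<unsigned char> T;

  for (int i = 0; i < nr; ++i) {
    const std::string rd = as<std::string>(reads[i]);
    const std::string &rf = refv[ref_idx[i] - 1];
    const char *rp = rd.c_str();
    const char *fp = rf.c_str();
    const int n = rd.size(), m = rf.size();
    const int anchor = anchor_pos[i];

    // rolling-row DP with a full byte traceback matrix; rows = reference
    // (m), cols = read (n). trace codes: 0 diag, 1 up (gap in read,
    // consumes ref), 2 left (gap in ref, consumes read).
    // Leading and trailing end gaps are free in BOTH sequences: the read
    // continues past the segment into the junction, and the germline 3'
    // (V) or 5' (J) end may be trimmed away by recombination. First
    // row/column initialised to 0 and the endpoint is the global maximum
    // over all cells; no interior reset, so this is a single contiguous
    // global alignment of the covered region.
    const size_t W = (size_t)(n + 1);
    H.assign(W, 0);          // previous/current row of best scores
    F.assign(W, NEG);        // vertical-gap layer, rolling
    T.assign((m + 1) * W, 0);
    int best = 0, ba = 0, bb = 0;
    for (int a = 1; a <= m; ++a) {
      const char ca = fp[a - 1];
      unsigned char *Tr = T.data() + a * W;
      int diag = H[0];       // H[a-1][0] == 0
      int eCur = NEG;        // E within the current row
      for (int b = 1; b <= n; ++b) {
        int e = eCur - ge, eo = H[b - 1] - go;   // H[b-1] is current row
        if (eo > e) e = eo;
        int f = F[b] - ge, fo = H[b] - go;       // H[b], F[b] are prev row
        if (fo > f) f = fo;
        int d = diag + (base_match(ca, rp[b - 1]) ? match : mismatch);
        int h = d; unsigned char t = 0;
        if (f > h) { h = f; t = 1; }
        if (e > h) { h = e; t = 2; }
        diag = H[b];
        H[b] = h; F[b] = f; eCur = e; Tr[b] = t;
        if (h > best) { best = h; ba = a; bb = b; }
      }
    }

    int a = ba, b = bb, nmatch = 0, alen = 0, anch = NA_INTEGER;
    int rref_end = a, rread_end = b;
    while (a > 0 && b > 0) {
      const unsigned char t = T[a * W + b];
      if (t == 0) {
        if (base_match(fp[a - 1], rp[b - 1])) ++nmatch;
        if (a == anchor) anch = b;
        --a; --b;
      } else if (t == 1) {
        --a;
      } else {
        --b;
      }
      ++alen;
    }
    int rref_start = a + 1, rread_start = b + 1;

    // greedy matched extension toward the junction
    if (extend_right) {
      while (rref_end < m && rread_end < n &&
             base_match(fp[rref_end], rp[rread_end])) {
        ++rref_end; ++rread_end; ++nmatch; ++alen;
        if (rref_end == anchor) anch = rread_end;
      }
    } else {
      while (rref_start > 1 && rread_start > 1 &&
             base_match(fp[rref_start - 2], rp[rread_start - 2])) {
        --rref_start; --rread_start; ++nmatch; ++alen;
        if (rref_start == anchor) anch = rread_start;
      }
    }

    score[i] = best;
    read_start[i] = rread_start; read_end[i] = rread_end;
    ref_start[i] = rref_start;   ref_end[i] = rref_end;
    matches[i] = nmatch; aln_len[i] = alen; anchor_read[i] = anch;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(
      _["score"] = score,
      _["read_start"] = read_start, _["read_end"] = read_end,
      _["ref_start"] = ref_start, _["ref_end"] = ref_end,
      _["matches"] = matches, _["aln_len"] = aln_len,
      _["anchor_read"] = anchor_read);
}

// D-segment calling inside junction sequences: best contiguous germline-D
// substring of length >= min_len present in the junction with <= max_mm
// mismatches. Preference order: longer match, fewer mismatches, earlier D in
// database order, leftmost junction position, leftmost D offset.
//' @noRd
// [[Rcpp::export(name = ".cpp_call_d")]]
DataFrame cpp_call_d(CharacterVector junctions, CharacterVector d_seqs,
                     int min_len, int max_mm) {
  const int nj = junctions.size(), nd = d_seqs.size();
  std::vector<std::string> dv(nd);
  for (int k = 0; k < nd; ++k) dv[k] = as<std::string>(d_seqs[k]);
  IntegerVector d_index(nj), d_len(nj), d_mm(nj);
  for (int i = 0; i < nj; ++i) {
    const std::string ju = as<std::string>(junctions[i]);
    const int L = ju.size();
    int bi = NA_INTEGER, blen = 0, bmm = 0;
    for (int k = 0; k < nd; ++k) {
      const std::string &D = dv[k];
      const int dl = D.size();
      const int maxw = std::min(dl, L);
      for (int w = maxw; w >= min_len; --w) {
        if (bi != NA_INTEGER && w < blen) break;
        for (int t = 0; t + w <= L; ++t) {
          for (int s = 0; s + w <= dl; ++s) {
            int mm = 0;
            for (int p = 0; p < w && mm <= max_mm; ++p)
              if (!base_match(D[s + p], ju[t + p])) ++mm;
            if (mm <= max_mm) {
              const bool better = (bi == NA_INTEGER) || (w > blen) ||
                                  (w == blen && mm < bmm);
              if (better) { bi = k + 1; blen = w; bmm = mm; }
            }
          }
        }
      }
    }
    d_index[i] = bi; d_len[i] = (bi == NA_INTEGER) ? NA_INTEGER : blen;
    d_mm[i] = (bi == NA_INTEGER) ? NA_INTEGER : bmm;
  }
  return DataFrame::create(_["d_index"] = d_index, _["d_len"] = d_len,
                           _["d_mm"] = d_mm);
}

// RSS window scan on the forward strand of one contig: every position where
// heptamer (within hmax mismatches), an allowed spacer, and nonamer (within
// nmax mismatches) occur in succession. Windows containing characters other
// than ACGTN are rejected; N counts as a mismatch.
//' @noRd
// [[Rcpp::export(name = ".cpp_rss_scan")]]
DataFrame cpp_rss_scan(std::string seq, std::string heptamer,
                       std::string nonamer, IntegerVector spacers,
                       int hmax, int nmax) {
  const int L = seq.size(), hl = heptamer.size(), nl = nonamer.size();
  std::vector<int> pos, spc, hmm, nmm;
  std::vector<bool> valid(L, true);
  for (int i = 0; i < L; ++i) {
    const char c = seq[i];
    valid[i] = (c == 'A' || c == 'C' || c == 'G' || c == 'T' || c == 'N');
  }
  for (int i = 0; i + hl <= L; ++i) {
    int hm = 0; bool ok = true;
    for (int p = 0; p < hl; ++p) {
      if (!valid[i + p]) { ok = false; break; }
      if (!base_match(seq[i + p], heptamer[p])) ++hm;
      if (hm > hmax) { ok = false; break; }
    }
    if (!ok) continue;
    for (int si = 0; si < spacers.size(); ++si) {
      const int sp = spacers[si];
      const int j = i + hl + sp;
      if (j + nl > L) continue;
      bool wok = true;
      for (int p = i + hl; p < j; ++p) if (!valid[p]) { wok = false; break; }
      if (!wok) continue;
      int nm = 0;
      for (int p = 0; p < nl; ++p) {
        if (!valid[j + p]) { wok = false; break; }
        if (!base_match(seq[j + p], nonamer[p])) ++nm;
        if (nm > nmax) { wok = false; break; }
      }
      if (!wok) continue;
      pos.push_back(i + 1); spc.push_back(sp);
      hmm.push_back(hm); nmm.push_back(nm);
    }
  }
  return DataFrame::create(_["start"] = wrap(pos), _["spacer"] = wrap(spc),
                           _["heptamer_mm"] = wrap(hmm),
                           _["nonamer_mm"] = wrap(nmm));
}
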