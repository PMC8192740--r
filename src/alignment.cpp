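#include <Rcpp.h>
#include <unordered_map>
#include <deque>
#include <vector>
using namespace Rcpp;

// Alignment kernels. Protein residues are integer codes indexing the
// substitution matrix (row = query residue, col = subject residue).
// Nucleotides are coded A=0, C=1, G=2, T=3, N=4.

static inline double submat_at(const NumericMatrix& mat, int a, int b) {
    return mat(a, b);
}

// ---------------------------------------------------------------------------
// Affine-gap Smith-Waterman, local. Gap of length L costs gapOpen + L*gapExt
// (NCBI convention: opening a gap costs gapOpen + gapExt for the first char).
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, NumericMatrix mat,
                  double gapOpen, double gapExt, bool traceback) {
    const int m = q.size(), n = s.size();
    const double ninf = -1e30;
    const double go = gapOpen + gapExt, ge = gapExt;

    if (m == 0 || n == 0)
        return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = -1,
                            _["s_start"] = 0, _["s_end"] = -1);

    double best = 0.0;
    int bi = 0, bj = 0;

    if (!traceback) {
        std::vector<double> H(n + 1, 0.0), E(n + 1, ninf);
        for (int i = 1; i <= m; ++i) {
            double diagPrev = 0.0;  // H[i-1][0]
            double F = ninf;
            double Hij0 = 0.0;      // H[i][0]
            double prevH = Hij0;
            for (int j = 1; j <= n; ++j) {
                double e = std::max(H[j] - go, E[j] - ge);       // gap in subj dim? (vertical)
                // NOTE: with rolling rows, E[j] tracks gaps consuming query rows
                F = std::max(prevH - go, F - ge);                // gap consuming subject
                double h = diagPrev + submat_at(mat, q[i - 1], s[j - 1]);
                h = std::max(h, e);
                h = std::max(h, F);
                h = std::max(h, 0.0);
                diagPrev = H[j];
                H[j] = h;
                E[j] = e;
                prevH = h;
                if (h > best) { best = h; bi = i; bj = j; }
            }
        }
        return List::create(_["score"] = best, _["q_start"] = 0, _["q_end"] = bi,
                            _["s_start"] = 0, _["s_end"] = bj);
    }

    // Full matrices with traceback pointers.
    std::vector<double> H((size_t)(m + 1) * (n + 1), 0.0);
    std::vector<double> E((size_t)(m + 1) * (n + 1), ninf);
    std::vector<double> F((size_t)(m + 1) * (n + 1), ninf);
    std::vector<unsigned char> TB((size_t)(m + 1) * (n + 1), 0); // 0 stop,1 diag,2 up(E),3 left(F)
    std::vector<unsigned char> TE((size_t)(m + 1) * (n + 1), 0); // 1 = extend
    std::vector<unsigned char> TF((size_t)(m + 1) * (n + 1), 0);
    auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            double eo = H[idx(i - 1, j)] - go, ee = E[idx(i - 1, j)] - ge;
            double e = std::max(eo, ee);
            TE[idx(i, j)] = (ee > eo) ? 1 : 0;
            double fo = H[idx(i, j - 1)] - go, fe = F[idx(i, j - 1)] - ge;
            double f = std::max(fo, fe);
            TF[idx(i, j)] = (fe > fo) ? 1 : 0;
            double d = H[idx(i - 1, j - 1)] + submat_at(mat, q[i - 1], s[j - 1]);
            double h = 0.0; unsigned char t = 0;
            if (d > h) { h = d; t = 1; }
            if (e > h) { h = e; t = 2; }
            if (f > h) { h = f; t = 3; }
            H[idx(i, j)] = h; E[idx(i, j)] = e; F[idx(i, j)] = f; TB[idx(i, j)] = t;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }

    // Traceback from best cell.
    int i = bi, j = bj;
    std::vector<int> qa, sa; // aligned pairs (1-based, -1 for gap)
    int state = 0; // 0 = in H
    while (i > 0 && j > 0) {
        if (state == 0) {
            unsigned char t = TB[idx(i, j)];
            if (t == 0) break;
            if (t == 1) { qa.push_back(i); sa.push_back(j); --i; --j; }
            else if (t == 2) state = 2;
            else state = 3;
        } else if (state == 2) {
            qa.push_back(i); sa.push_back(-1);
            bool ext = TE[idx(i, j)] == 1;
            --i;
            if (!ext) state = 0;
        } else {
            qa.push_back(-1); sa.push_back(j);
            bool ext = TF[idx(i, j)] == 1;
            --j;
            if (!ext) state = 0;
        }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(sa.begin(), sa.end());
    int qs = m + 1, ss = n + 1;
    for (size_t k = 0; k < qa.size(); ++k) if (qa[k] > 0) { qs = qa[k]; break; }
    for (size_t k = 0; k < sa.size(); ++k) if (sa[k] > 0) { ss = sa[k]; break; }
    return List::create(_["score"] = best,
                        _["q_start"] = qs, _["q_end"] = bi,
                        _["s_start"] = ss, _["s_end"] = bj,
                        _["q_aligned"] = IntegerVector(qa.begin(), qa.end()),
                        _["s_aligned"] = IntegerVector(sa.begin(), sa.end()));
}

// ---------------------------------------------------------------------------
// Two-hit seed finder: exact word matches of length `word` between query and
// subject; two hits on the same diagonal within `window` residues trigger a
// candidate region. Returns a matrix with one row per two-hit event:
// (subject start of first hit, subject end of second hit) 0-based half-open.
// [[Rcpp::export]]
IntegerMatrix seed_windows_cpp(IntegerVector q, IntegerVector s, int word,
                               int window) {
    const int m = q.size(), n = s.size();
    std::vector<std::pair<int, int> > events;
    if (m >= word && n >= word) {
        // word keys over residue codes (codes < 64 assumed)
        std::unordered_map<long long, std::vector<int> > qwords;
        for (int p = 0; p + word <= m; ++p) {
            long long key = 0;
            for (int k = 0; k < word; ++k) key = key * 64 + q[p + k];
            qwords[key].push_back(p);
        }
        std::unordered_map<int, int> lastpos; // diagonal -> last hit subject pos
        for (int j = 0; j + word <= n; ++j) {
            long long key = 0;
            for (int k = 0; k < word; ++k) key = key * 64 + s[j + k];
            auto it = qwords.find(key);
            if (it == qwords.end()) continue;
            for (int p : it->second) {
                int diag = j - p;
                auto lp = lastpos.find(diag);
                if (lp != lastpos.end() && j > lp->second &&
                    j - lp->second <= window) {
                    events.push_back(std::make_pair(lp->second, j + word));
                }
                lastpos[diag] = j;
            }
        }
    }
    IntegerMatrix out(events.size(), 2);
    for (size_t k = 0; k < events.size(); ++k) {
        out(k, 0) = events[k].first;
        out(k, 1) = events[k].second;
    }
    return out;
}

// ---------------------------------------------------------------------------
// Frameshift-aware local alignment of a reference protein against a
// nucleotide candidate region. Moves into cell (i, j):
//   diag3: consume 1 residue + 3 nt (codon match)
//   fs2:   consume 1 residue + 2 nt (deletion frameshift), penalty fsPen,
//          residue scored against the best completion codon
//   fs4:   consume 1 residue + 4 nt (insertion frameshift), penalty fsPen,
//          residue scored against the best 3-of-4 codon
//   del:   consume 1 residue, 0 nt (residue unaligned), penalty gapRes
//   ins:   consume 0 residues, 3 nt (extra codon), penalty gapRes
// codonTab: length-64 lookup 16*b1+4*b2+b3 -> residue code; xCode used for
// codons containing N; stopCode identifies stop codons.
// [[Rcpp::export]]
List fs_align_cpp(IntegerVector prot, IntegerVector dna, NumericMatrix mat,
                  IntegerVector codonTab, int xCode, int stopCode,
                  double fsPen, double gapRes, bool tieRight) {
    const int m = prot.size(), n = dna.size();
    auto codon = [&](int a, int b, int c) -> int {
        if (a > 3 || b > 3 || c > 3) return xCode;
        return codonTab[16 * a + 4 * b + c];
    };
    const double ninf = -1e30;
    std::vector<double> H((size_t)(m + 1) * (n + 1), 0.0);
    std::vector<unsigned char> TB((size_t)(m + 1) * (n + 1), 0);
    // TB codes: 0 stop, 1 diag3, 2 fs2, 3 fs4, 4 del, 5 ins
    auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
    double best = 0.0; int bi = 0, bj = 0;

    for (int i = 1; i <= m; ++i) {
        const int r = prot[i - 1];
        for (int j = 0; j <= n; ++j) {
            double h = 0.0; unsigned char t = 0;
            if (j >= 3) {
                int aa = codon(dna[j - 3], dna[j - 2], dna[j - 1]);
                double d = H[idx(i - 1, j - 3)] + submat_at(mat, r, aa);
                if (d > h) { h = d; t = 1; }
            }
            if (j >= 2) {
                // best completion codon: insert any base at any of 3 positions
                double bsc = ninf;
                for (int x = 0; x < 4; ++x) {
                    int c1 = codon(x, dna[j - 2], dna[j - 1]);
                    int c2 = codon(dna[j - 2], x, dna[j - 1]);
                    int c3 = codon(dna[j - 2], dna[j - 1], x);
                    bsc = std::max(bsc, submat_at(mat, r, c1));
                    bsc = std::max(bsc, submat_at(mat, r, c2));
                    bsc = std::max(bsc, submat_at(mat, r, c3));
                }
                double d = H[idx(i - 1, j - 2)] + bsc - fsPen;
                // tieRight: on ties prefer the frameshift at the later
                // residue, resolving co-optimal placements to the rightmost
                // one; otherwise to the leftmost (the two passes bound the
                // placement-ambiguity interval of a lesion)
                if ((tieRight && d >= h && d > 0) || (!tieRight && d > h)) {
                    h = d; t = 2;
                }
            }
            if (j >= 4) {
                // best 3-of-4 codon: drop one of the four nucleotides
                int b1 = dna[j - 4], b2 = dna[j - 3], b3 = dna[j - 2],
                    b4 = dna[j - 1];
                double bsc = submat_at(mat, r, codon(b2, b3, b4));
                bsc = std::max(bsc, submat_at(mat, r, codon(b1, b3, b4)));
                bsc = std::max(bsc, submat_at(mat, r, codon(b1, b2, b4)));
                bsc = std::max(bsc, submat_at(mat, r, codon(b1, b2, b3)));
                double d = H[idx(i - 1, j - 4)] + bsc - fsPen;
                if ((tieRight && d >= h && d > 0) || (!tieRight && d > h)) {
                    h = d; t = 3;
                }
            }
            {
                double d = H[idx(i - 1, j)] - gapRes;
                if (d > h) { h = d; t = 4; }
            }
            if (j >= 3) {
                double d = H[idx(i, j - 3)] - gapRes;
                if (d > h) { h = d; t = 5; }
            }
            H[idx(i, j)] = h; TB[idx(i, j)] = t;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }

    // Traceback: collect lesions and coverage.
    int i = bi, j = bj;
    int covered = 0;
    std::vector<int> lesType, lesRef, lesDna; // type 1 = stop, 2 = frameshift
    while (i > 0 || j > 0) {
        unsigned char t = TB[idx(i, j)];
        if (t == 0) break;
        if (t == 1) {
            int aa = codon(dna[j - 3], dna[j - 2], dna[j - 1]);
            if (aa == stopCode) { lesType.push_back(1); lesRef.push_back(i); lesDna.push_back(j - 3); }
            ++covered; --i; j -= 3;
        } else if (t == 2) {
            lesType.push_back(2); lesRef.push_back(i); lesDna.push_back(j - 2);
            ++covered; --i; j -= 2;
        } else if (t == 3) {
            lesType.push_back(2); lesRef.push_back(i); lesDna.push_back(j - 4);
            ++covered; --i; j -= 4;
        } else if (t == 4) {
            --i;
        } else {
            j -= 3;
        }
    }
    return List::create(_["score"] = best,
                        _["ref_start"] = i + 1, _["ref_end"] = bi,
                        _["dna_start"] = j, _["dna_end"] = bj,
                        _["covered"] = covered,
                        _["lesion_type"] = IntegerVector(lesType.rbegin(), lesType.rend()),
                        _["lesion_ref"] = IntegerVector(lesRef.rbegin(), lesRef.rend()),
                        _["lesion_dna"] = IntegerVector(lesDna.rbegin(), lesDna.rend()));
}

// ---------------------------------------------------------------------------
// Spliced read alignment: best contiguous or two-block placement of a read on
// the locus. Blocks >= minAnchor; gap (intron) length within
// [minIntron, maxIntron]; placement minimizing mismatches; ties prefer
// contiguous, then canonical GT..AG introns, then smallest coordinates.
// N mismatches everything. Returns 0-based starts.
// [[Rcpp::export]]
List spliced_align_cpp(IntegerVector read, IntegerVector locus, int minAnchor,
                       int maxMismatch, int minIntron, int maxIntron) {
    const int r = read.size(), L = locus.size();
    // candidate: mism, spliced(0/1), noncanon(0/1), start, split(or r)
    long bestKey[5] = {long(maxMismatch) + 1, 0, 0, 0, 0};
    bool found = false;
    int bStart = -1, bSplit = -1, bJ = -1;
    bool bCanon = false;

    auto better = [&](long mism, long spliced, long noncanon, long start,
                      long split) {
        long cand[5] = {mism, spliced, noncanon, start, split};
        for (int k = 0; k < 5; ++k) {
            if (cand[k] < bestKey[k]) return true;
            if (cand[k] > bestKey[k]) return false;
        }
        return false;
    };
    auto mism = [&](int a, int b) -> int {
        return (a > 3 || b > 3 || a != b) ? 1 : 0;
    };

    // contiguous placements
    for (int i = 0; i + r <= L; ++i) {
        int mm = 0;
        for (int k = 0; k < r; ++k) {
            mm += mism(read[k], locus[i + k]);
            if (mm > maxMismatch) break;
        }
        if (mm <= maxMismatch && better(mm, 0, 0, i, r)) {
            bestKey[0] = mm; bestKey[1] = 0; bestKey[2] = 0;
            bestKey[3] = i; bestKey[4] = r;
            found = true; bStart = i; bSplit = r; bJ = -1; bCanon = false;
        }
    }

    if (r >= 2 * minAnchor && L > r) {
        std::vector<int> Ls(L, 0), Rs(L + 1, 0);
        // initialise for split = minAnchor
        int s0 = minAnchor;
        for (int i = 0; i + s0 <= L; ++i) {
            int mm = 0;
            for (int k = 0; k < s0; ++k) mm += mism(read[k], locus[i + k]);
            Ls[i] = mm;
        }
        for (int j = 0; j + (r - s0) <= L; ++j) {
            int mm = 0;
            for (int k = 0; k < r - s0; ++k) mm += mism(read[s0 + k], locus[j + k]);
            Rs[j] = mm;
        }
        for (int s = s0; s <= r - minAnchor; ++s) {
            if (s > s0) {
                // extend left prefix by one, shrink right suffix from front
                for (int i = 0; i + s <= L; ++i)
                    Ls[i] += mism(read[s - 1], locus[i + s - 1]);
                // Rs_new[j] = Rs_old[j-1] - mism(read[s-1], locus[j-1])
                for (int j = L - (r - s); j >= 1; --j)
                    Rs[j] = Rs[j - 1] - mism(read[s - 1], locus[j - 1]);
                Rs[0] = 0; // j = 0 invalid for spliced anyway (needs intron)
            }
            const int maxJ = L - (r - s); // last valid right-block start
            // deque over j of (Rs[j]); window for left start i: j in
            // [i+s+minIntron, i+s+maxIntron]
            std::deque<int> dqAll, dqAG;
            int nextPush = 0;
            for (int i = 0; i + s <= L; ++i) {
                int g = i + s;                 // intron start
                long lo = (long)g + minIntron;
                long hi = std::min((long)g + maxIntron, (long)maxJ);
                if (lo > hi) continue;
                while (nextPush <= hi) {
                    int j = nextPush++;
                    if (j < lo && i == 0) { /* still push; fronts popped below */ }
                    while (!dqAll.empty() && Rs[dqAll.back()] > Rs[j])
                        dqAll.pop_back();
                    dqAll.push_back(j);
                    if (j >= 2 && locus[j - 2] == 0 && locus[j - 1] == 2) {
                        while (!dqAG.empty() && Rs[dqAG.back()] > Rs[j])
                            dqAG.pop_back();
                        dqAG.push_back(j);
                    }
                }
                while (!dqAll.empty() && dqAll.front() < lo) dqAll.pop_front();
                while (!dqAG.empty() && dqAG.front() < lo) dqAG.pop_front();
                if (Ls[i] > maxMismatch) continue;
                bool donorGT = (g + 1 < L && locus[g] == 2 && locus[g + 1] == 3);
                // canonical candidate first (preferred on mismatch ties)
                if (donorGT && !dqAG.empty()) {
                    int j = dqAG.front();
                    int mm = Ls[i] + Rs[j];
                    if (mm <= maxMismatch && better(mm, 1, 0, i, s)) {
                        bestKey[0] = mm; bestKey[1] = 1; bestKey[2] = 0;
                        bestKey[3] = i; bestKey[4] = s;
                        found = true; bStart = i; bSplit = s; bJ = j; bCanon = true;
                    }
                }
                if (!dqAll.empty()) {
                    int j = dqAll.front();
                    int mm = Ls[i] + Rs[j];
                    bool canon = donorGT && j >= 2 && locus[j - 2] == 0 &&
                                 locus[j - 1] == 2;
                    if (mm <= maxMismatch &&
                        better(mm, 1, canon ? 0 : 1, i, s)) {
                        bestKey[0] = mm; bestKey[1] = 1; bestKey[2] = canon ? 0 : 1;
                        bestKey[3] = i; bestKey[4] = s;
                        found = true; bStart = i; bSplit = s; bJ = j; bCanon = canon;
                    }
                }
            }
        }
    }

    if (!found) return List::create(_["found"] = false);
    if (bJ < 0)
        return List::create(_["found"] = true, _["n_blocks"] = 1,
                            _["starts"] = IntegerVector::create(bStart),
                            _["sizes"] = IntegerVector::create(r),
                            _["mismatches"] = (int)bestKey[0],
                            _["canonical"] = NA_LOGICAL);
    return List::create(_["found"] = true, _["n_blocks"] = 2,
                        _["starts"] = IntegerVector::create(bStart, bJ),
                        _["sizes"] = IntegerVector::create(bSplit, r - bSplit),
                        _["mismatches"] = (int)bestKey[0],
                        _["canonical"] = bCanon);
}
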