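#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Deterministic BLASTN stand-in: exact k-mer seeding, diagonal clustering,
// banded Smith-Waterman extension with traceback. Linear gap penalty.
// Coordinates are 0-based internally; the R layer emits 1-based inclusive.

namespace {

const int CODE_N = 4;

std::vector<uint8_t> encode(const std::string &s) {
    std::vector<uint8_t> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) {
        switch (s[i]) {
        case 'A': case 'a': v[i] = 0; break;
        case 'C': case 'c': v[i] = 1; break;
        case 'G': case 'g': v[i] = 2; break;
        case 'T': case 't': v[i] = 3; break;
        case 'N': case 'n': v[i] = CODE_N; break;
        default:
            stop("non-nucleotide character '%s' in sequence",
                 std::string(1, s[i]).c_str());
        }
    }
    return v;
}

std::vector<uint8_t> revcomp(const std::vector<uint8_t> &v) {
    std::vector<uint8_t> r(v.size());
    for (size_t i = 0; i < v.size(); ++i) {
        uint8_t b = v[v.size() - 1 - i];
        r[i] = (b == CODE_N) ? CODE_N : (uint8_t)(3 - b);
    }
    return r;
}

// k-mers containing N are skipped (no seed through ambiguity)
inline bool kmer_at(const std::vector<uint8_t> &s, int pos, int k, uint64_t &key) {
    uint64_t v = 0;
    for (int i = 0; i < k; ++i) {
        uint8_t b = s[pos + i];
        if (b == CODE_N) return false;
        v = (v << 2) | b;
    }
    key = v;
    return true;
}

struct Aln {
    int score = -1;
    int matches = 0;
    int columns = 0;       // alignment columns incl. gaps
    int qstart = 0, qend = 0;  // 0-based half-open on query
    int tstart = 0, tend = 0;  // 0-based half-open on target
    bool valid() const { return score >= 0; }
};

// Banded local alignment restricted to diagonals d = j - i in [dlo, dhi]
// (i: query index, j: target index, both 0-based). Traceback recovers
// matches, alignment columns and spans of the single best-scoring cell.
Aln banded_sw(const std::vector<uint8_t> &q, const std::vector<uint8_t> &t,
              int dlo, int dhi, int match, int mismatch, int gap) {
    const int m = (int)q.size(), n = (int)t.size();
    dlo = std::max(dlo, -(m - 1));
    dhi = std::min(dhi, n - 1);
    Aln best;
    if (dlo > dhi) return best;
    const int w = dhi - dlo + 3;  // sentinel column on each side
    // H[(i)*(w) + (d - dlo + 1)] for i in 0..m
    std::vector<int> H((size_t)(m + 1) * w, 0);
    std::vector<uint8_t> TB((size_t)(m + 1) * w, 0);  // 0 stop, 1 diag, 2 up(qgap in t), 3 left
    int bi = -1, bd = 0, bs = 0;
    for (int i = 1; i <= m; ++i) {
        int jlo = std::max(1, i + dlo), jhi = std::min(n, i + dhi);
        for (int j = jlo; j <= jhi; ++j) {
            const int d = j - i;
            const size_t idx = (size_t)i * w + (d - dlo + 1);
            // diag: (i-1, j-1), same d
            uint8_t qb = q[i - 1], tb = t[j - 1];
            int sub = (qb != CODE_N && qb == tb) ? match : mismatch;
            int sc_diag = H[(size_t)(i - 1) * w + (d - dlo + 1)] + sub;
            // up: (i-1, j) -> d + 1 (gap in target / consumes query base)
            int sc_up = (d + 1 <= dhi) ?
                H[(size_t)(i - 1) * w + (d + 1 - dlo + 1)] + gap : INT32_MIN / 2;
            // left: (i, j-1) -> d - 1 (gap in query / consumes target base)
            int sc_left = (d - 1 >= dlo) ?
                H[(size_t)i * w + (d - 1 - dlo + 1)] + gap : INT32_MIN / 2;
            int sc = sc_diag; uint8_t tb_op = 1;
            if (sc_up > sc) { sc = sc_up; tb_op = 2; }
            if (sc_left > sc) { sc = sc_left; tb_op = 3; }
            if (sc <= 0) { sc = 0; tb_op = 0; }
            H[idx] = sc;
            TB[idx] = tb_op;
            if (sc > bs) { bs = sc; bi = i; bd = d; }
        }
    }
    if (bi < 0) return best;
    // traceback from (bi, bd)
    int i = bi, d = bd;
    int matches = 0, columns = 0;
    int qend = bi, tend = bi + bd;  // half-open ends
    while (i > 0) {
        size_t idx = (size_t)i * w + (d - dlo + 1);
        uint8_t op = TB[idx];
        if (op == 0 || H[idx] == 0) break;
        int j = i + d;
        if (op == 1) {
            ++columns;
            uint8_t qb = q[i - 1];
            if (qb != CODE_N && qb == t[j - 1]) ++matches;
            --i;  // d unchanged
        } else if (op == 2) {
            ++columns; --i; ++d;
        } else {
            ++columns; --d;
        }
    }
    best.score = bs;
    best.matches = matches;
    best.columns = columns;
    best.qstart = i;
    best.qend = qend;
    best.tstart = i + d;
    best.tend = tend;
    return best;
}

// Collect seed diagonals of q against t, cluster diagonals closer than
// `band`, run a banded extension per cluster, return the best alignment.
Aln seed_and_extend(const std::vector<uint8_t> &q, const std::vector<uint8_t> &t,
                    int k, int band, int match, int mismatch, int gap,
                    int max_kmer_occ = 64) {
    Aln best;
    const int m = (int)q.size(), n = (int)t.size();
    if (m < k || n < k) return best;
    std::unordered_map<uint64_t, std::vector<int>> index;
    index.reserve(n * 2);
    uint64_t key;
    for (int j = 0; j + k <= n; ++j)
        if (kmer_at(t, j, k, key)) index[key].push_back(j);
    std::vector<int> diags;
    for (int i = 0; i + k <= m; ++i) {
        if (!kmer_at(q, i, k, key)) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        if ((int)it->second.size() > max_kmer_occ) continue;
        for (int j : it->second) diags.push_back(j - i);
    }
    if (diags.empty()) return best;
    std::sort(diags.begin(), diags.end());
    diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
    size_t s = 0;
    for (size_t e = 1; e <= diags.size(); ++e) {
        if (e == diags.size() || diags[e] - diags[e - 1] > 2 * band) {
            Aln a = banded_sw(q, t, diags[s] - band, diags[e - 1] + band,
                              match, mismatch, gap);
            if (a.valid() && a.score > best.score) best = a;
            s = e;
        }
    }
    return best;
}

struct BestHit {
    int target = -1;       // index into target set
    int strand = 1;        // +1 / -1
    Aln aln;
};

// flip half-open query coordinates from the reverse-complemented query
// back onto the original query
inline void flip_query_coords(Aln &a, int qlen) {
    int qs = qlen - a.qend, qe = qlen - a.qstart;
    a.qstart = qs; a.qend = qe;
}

double identity_pct(const Aln &a) {
    return a.columns > 0 ? 100.0 * a.matches / a.columns : 0.0;
}

// tie_mode 0: higher identity, then longer aligned_length, then smallest
//             target id (lexicographic) — cross-assembler comparison
// tie_mode 1: smallest target id, then leftmost target start — read mapping
bool better_hit(const BestHit &cand, const BestHit &cur,
                const std::vector<std::string> &ids, int tie_mode) {
    if (!cur.aln.valid()) return true;
    if (cand.aln.score != cur.aln.score) return cand.aln.score > cur.aln.score;
    if (tie_mode == 0) {
        double ic = identity_pct(cand.aln), iu = identity_pct(cur.aln);
        if (ic != iu) return ic > iu;
        if (cand.aln.columns != cur.aln.columns)
            return cand.aln.columns > cur.aln.columns;
        return ids[cand.target] < ids[cur.target];
    }
    if (cand.target != cur.target) return ids[cand.target] < ids[cur.target];
    return cand.aln.tstart < cur.aln.tstart;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_align_pair")]]
List cpp_align_pair(std::string query, std::string target, int k, int band,
                    int match, int mismatch, int gap, int min_score) {
    std::vector<uint8_t> q = encode(query), t = encode(target);
    Aln fwd = seed_and_extend(q, t, k, band, match, mismatch, gap);
    std::vector<uint8_t> qr = revcomp(q);
    Aln rev = seed_and_extend(qr, t, k, band, match, mismatch, gap);
    bool use_rev = rev.valid() && (!fwd.valid() || rev.score > fwd.score);
    Aln best = use_rev ? rev : fwd;
    if (!best.valid() || best.score < min_score)
        return List::create(_["matched"] = false);
    if (use_rev) flip_query_coords(best, (int)q.size());
    return List::create(
        _["matched"] = true,
        _["score"] = best.score,
        _["matches"] = best.matches,
        _["aligned_length"] = best.columns,
        _["identity"] = identity_pct(best),
        _["strand"] = use_rev ? "-" : "+",
        _["qstart"] = best.qstart + 1, _["qend"] = best.qend,
        _["tstart"] = best.tstart + 1, _["tend"] = best.tend);
}

// Cross-hybridization screen: for each probe, does ANY non-parent target
// carry a local alignment with identity >= min_identity over >=
// min_span columns? Returns the first offending target id (or NA).
// [[Rcpp::export(name = ".cpp_offtarget")]]
CharacterVector cpp_offtarget(CharacterVector probes,
                              CharacterVector parent_ids,
                              CharacterVector targets,
                              CharacterVector target_ids,
                              int k, int band, int match, int mismatch,
                              int gap, double min_identity, int min_span) {
    const int nt = targets.size(), np = probes.size();
    std::vector<std::vector<uint8_t>> tenc(nt);
    std::vector<std::string> tids(nt);
    std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
    uint64_t key;
    for (int ti = 0; ti < nt; ++ti) {
        tenc[ti] = encode(as<std::string>(targets[ti]));
        tids[ti] = as<std::string>(target_ids[ti]);
        const auto &t = tenc[ti];
        for (int j = 0; j + k <= (int)t.size(); ++j)
            if (kmer_at(t, j, k, key)) index[key].emplace_back(ti, j);
    }
    CharacterVector out(np);
    for (int pi = 0; pi < np; ++pi) {
        std::string parent = as<std::string>(parent_ids[pi]);
        std::vector<uint8_t> q = encode(as<std::string>(probes[pi]));
        std::vector<uint8_t> qr = revcomp(q);
        out[pi] = NA_STRING;
        bool found = false;
        for (int pass = 0; pass < 2 && !found; ++pass) {
            const std::vector<uint8_t> &qq = (pass == 0) ? q : qr;
            std::vector<char> seen(nt, 0);
            std::vector<int> cands;
            for (int i = 0; i + k <= (int)qq.size(); ++i) {
                if (!kmer_at(qq, i, k, key)) continue;
                auto it = index.find(key);
                if (it == index.end()) continue;
                for (auto &pr : it->second)
                    if (!seen[pr.first]) { seen[pr.first] = 1; cands.push_back(pr.first); }
            }
            std::sort(cands.begin(), cands.end(),
                [&](int a, int b) { return tids[a] < tids[b]; });
            for (int ti : cands) {
                if (tids[ti] == parent) continue;
                Aln a = seed_and_extend(qq, tenc[ti], k, band, match,
                                        mismatch, gap);
                if (a.valid() && a.columns >= min_span &&
                        identity_pct(a) >= min_identity) {
                    out[pi] = tids[ti];
                    found = true;
                    break;
                }
            }
        }
    }
    return out;
}

// One best hit per query across a target set. A shared global k-mer index
// nominates candidate targets; only nominated pairs are extended.
// [[Rcpp::export(name = ".cpp_best_matches")]]
DataFrame cpp_best_matches(CharacterVector queries, CharacterVector query_ids,
                           CharacterVector targets, CharacterVector target_ids,
                           int k, int band, int match, int mismatch, int gap,
                           int min_score, bool exclude_same_id, int tie_mode) {
    const int nt = targets.size(), nq = queries.size();
    std::vector<std::vector<uint8_t>> tenc(nt);
    std::vector<std::string> tids(nt);
    std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
    uint64_t key;
    for (int ti = 0; ti < nt; ++ti) {
        tenc[ti] = encode(as<std::string>(targets[ti]));
        tids[ti] = as<std::string>(target_ids[ti]);
        const auto &t = tenc[ti];
        for (int j = 0; j + k <= (int)t.size(); ++j)
            if (kmer_at(t, j, k, key)) index[key].emplace_back(ti, j);
    }
    CharacterVector out_q(nq), out_t(nq), out_strand(nq);
    NumericVector out_id(nq);
    IntegerVector out_alen(nq), out_score(nq),
        out_qs(nq), out_qe(nq), out_ts(nq), out_te(nq);
    LogicalVector out_matched(nq);

    for (int qi = 0; qi < nq; ++qi) {
        std::string qid = as<std::string>(query_ids[qi]);
        std::vector<uint8_t> q = encode(as<std::string>(queries[qi]));
        std::vector<uint8_t> qr = revcomp(q);
        BestHit best;
        for (int pass = 0; pass < 2; ++pass) {
            const std::vector<uint8_t> &qq = (pass == 0) ? q : qr;
            // candidate targets sharing at least one k-mer
            std::vector<char> seen(nt, 0);
            std::vector<int> cands;
            for (int i = 0; i + k <= (int)qq.size(); ++i) {
                if (!kmer_at(qq, i, k, key)) continue;
                auto it = index.find(key);
                if (it == index.end()) continue;
                for (auto &pr : it->second)
                    if (!seen[pr.first]) { seen[pr.first] = 1; cands.push_back(pr.first); }
            }
            for (int ti : cands) {
                if (exclude_same_id && tids[ti] == qid) continue;
                Aln a = seed_and_extend(qq, tenc[ti], k, band, match, mismatch, gap);
                if (!a.valid() || a.score < min_score) continue;
                if (pass == 1) flip_query_coords(a, (int)q.size());
                BestHit cand; cand.target = ti; cand.strand = (pass == 0) ? 1 : -1;
                cand.aln = a;
                if (better_hit(cand, best, tids, tie_mode)) best = cand;
            }
        }
        out_q[qi] = qid;
        out_matched[qi] = best.aln.valid();
        if (best.aln.valid()) {
            out_t[qi] = tids[best.target];
            out_id[qi] = identity_pct(best.aln);
            out_alen[qi] = best.aln.columns;
            out_strand[qi] = best.strand > 0 ? "+" : "-";
            out_qs[qi] = best.aln.qstart + 1; out_qe[qi] = best.aln.qend;
            out_ts[qi] = best.aln.tstart + 1; out_te[qi] = best.aln.tend;
            out_score[qi] = best.aln.score;
        } else {
            out_t[qi] = NA_STRING;
            out_id[qi] = NA_REAL;
            out_alen[qi] = NA_INTEGER;
            out_strand[qi] = NA_STRING;
            out_qs[qi] = NA_INTEGER; out_qe[qi] = NA_INTEGER;
            out_ts[qi] = NA_INTEGER; out_te[qi] = NA_INTEGER;
            out_score[qi] = NA_INTEGER;
        }
    }
    return DataFrame::create(
        _["query_id"] = out_q, _["target_id"] = out_t,
        _["identity"] = out_id, _["aligned_length"] = out_alen,
        _["strand"] = out_strand,
        _["qstart"] = out_qs, _["qend"] = out_qe,
        _["tstart"] = out_ts, _["tend"] = out_te,
        _["score"] = out_score, _["matched"] = out_matched,
        _["stringsAsFactors"] = false);
}
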