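#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Flag (clique) filtration of a dense dissimilarity matrix and persistence
// by boundary-matrix column reduction over GF(2) with the twist (clearing)
// optimization: dimensions are reduced top-down so columns already paired as
// births are never reduced. Simplex order: (filtration value, dimension,
// lexicographic vertex tuple).

namespace {

// binomial table, n up to 512, k up to 5 (simplices up to tetrahedra)
static inline std::vector<std::vector<double>> binom_table(int n, int kmax) {
    std::vector<std::vector<double>> C(n + 1, std::vector<double>(kmax + 1, 0.0));
    for (int i = 0; i <= n; ++i) {
        C[i][0] = 1.0;
        for (int k = 1; k <= kmax && k <= i; ++k)
            C[i][k] = C[i - 1][k - 1] + (i - 1 >= k ? C[i - 1][k] : 0.0);
    }
    return C;
}

// lexicographic rank of sorted combo among all k-subsets of {0..n-1}
static inline int lex_rank(const int* v, int k, int n,
                           const std::vector<std::vector<double>>& C) {
    double r = 0.0;
    int prev = -1;
    for (int i = 0; i < k; ++i) {
        for (int x = prev + 1; x < v[i]; ++x)
            r += C[n - 1 - x][k - 1 - i];
        prev = v[i];
    }
    return (int)r;
}

struct Filtration {
    int N;
    int max_dim;                       // highest simplex dimension enumerated
    std::vector<std::vector<int>> verts;   // per dim: flattened vertex tuples
    std::vector<std::vector<double>> vals; // per dim: filtration values (lex order)
};

// enumerate all simplices up to max_dim; every off-diagonal entry is an edge
static Filtration enumerate_flag(const NumericMatrix& D, int max_dim) {
    const int N = D.nrow();
    Filtration F;
    F.N = N;
    F.max_dim = max_dim;
    F.verts.resize(max_dim + 1);
    F.vals.resize(max_dim + 1);

    // vertices
    F.verts[0].reserve(N);
    F.vals[0].assign(N, 0.0);
    for (int i = 0; i < N; ++i) F.verts[0].push_back(i);

    if (max_dim >= 1) {
        for (int i = 0; i < N; ++i)
            for (int j = i + 1; j < N; ++j) {
                F.verts[1].push_back(i);
                F.verts[1].push_back(j);
                F.vals[1].push_back(D(i, j));
            }
    }
    if (max_dim >= 2) {
        size_t nt = 0;
        for (int i = 0; i < N; ++i)
            for (int j = i + 1; j < N; ++j)
                for (int k = j + 1; k < N; ++k) {
                    double v = std::max(D(i, j), std::max(D(i, k), D(j, k)));
                    F.verts[2].push_back(i);
                    F.verts[2].push_back(j);
                    F.verts[2].push_back(k);
                    F.vals[2].push_back(v);
                    ++nt;
                }
        (void)nt;
    }
    if (max_dim >= 3) {
        for (int i = 0; i < N; ++i)
            for (int j = i + 1; j < N; ++j) {
                double dij = D(i, j);
                for (int k = j + 1; k < N; ++k) {
                    double dijk = std::max(dij, std::max(D(i, k), D(j, k)));
                    for (int l = k + 1; l < N; ++l) {
                        double v = std::max(dijk,
                            std::max(D(i, l), std::max(D(j, l), D(k, l))));
                        F.verts[3].push_back(i);
                        F.verts[3].push_back(j);
                        F.verts[3].push_back(k);
                        F.verts[3].push_back(l);
                        F.vals[3].push_back(v);
                    }
                }
            }
    }
    return F;
}

// symmetric difference of two sorted int vectors into out
static inline void symdiff(const std::vector<int>& a, const std::vector<int>& b,
                           std::vector<int>& out) {
    out.clear();
    size_t i = 0, j = 0;
    while (i < a.size() && j < b.size()) {
        if (a[i] < b[j]) out.push_back(a[i++]);
        else if (b[j] < a[i]) out.push_back(b[j++]);
        else { ++i; ++j; }
    }
    while (i < a.size()) out.push_back(a[i++]);
    while (j < b.size()) out.push_back(b[j++]);
}

} // namespace

// [[Rcpp::export]]
List cpp_flag_simplices(NumericMatrix D, int max_dim) {
    Filtration F = enumerate_flag(D, max_dim);
    List out(max_dim + 1);
    for (int d = 0; d <= max_dim; ++d) {
        int k = d + 1;
        int n = (int)F.vals[d].size();
        IntegerMatrix V(n, k);
        for (int s = 0; s < n; ++s)
            for (int c = 0; c < k; ++c)
                V(s, c) = F.verts[d][(size_t)s * k + c] + 1; // 1-based for R
        out[d] = List::create(_["vertices"] = V,
                              _["values"] = NumericVector(F.vals[d].begin(),
                                                          F.vals[d].end()));
    }
    return out;
}

// Persistence pairs via the coboundary (persistent cohomology) reduction
// with clearing: for each homology dimension d, the columns are the
// d-simplices in decreasing filtration order and the rows their
// (d+1)-cofacets. This computes the same pairing as boundary-matrix
// reduction but only ever reduces columns up to dimension max_hom_dim,
// which is what makes dense clique filtrations tractable: the vast
// majority of top-dimensional simplices are never touched as columns.
// [[Rcpp::export]]
NumericMatrix cpp_persistence(NumericMatrix D, int max_hom_dim) {
    const int N = D.nrow();
    const int max_dim = max_hom_dim + 1;
    Filtration F = enumerate_flag(D, max_dim);
    auto C = binom_table(N, max_dim + 2);

    // global filtration order: (value, dim, lex id)
    std::vector<size_t> ncum(max_dim + 2, 0);
    for (int d = 0; d <= max_dim; ++d)
        ncum[d + 1] = ncum[d] + F.vals[d].size();
    const size_t n_tot = ncum[max_dim + 1];

    struct Key { double v; int32_t dim; int32_t id; };
    std::vector<Key> keys(n_tot);
    for (int d = 0; d <= max_dim; ++d)
        for (size_t i = 0; i < F.vals[d].size(); ++i)
            keys[ncum[d] + i] = Key{F.vals[d][i], d, (int32_t)i};
    std::vector<uint32_t> order(n_tot);
    for (size_t i = 0; i < n_tot; ++i) order[i] = (uint32_t)i;
    std::sort(order.begin(), order.end(), [&](uint32_t a, uint32_t b) {
        if (keys[a].v != keys[b].v) return keys[a].v < keys[b].v;
        if (keys[a].dim != keys[b].dim) return keys[a].dim < keys[b].dim;
        return keys[a].id < keys[b].id;
    });
    std::vector<uint32_t> pos(n_tot); // (dim, lex id) -> filtration position
    for (size_t p = 0; p < n_tot; ++p) pos[order[p]] = (uint32_t)p;

    std::vector<double> out_dim, out_b, out_d;
    std::vector<char> cleared(n_tot, 0); // pivots of the previous dimension

    std::vector<int> col, tmp, rows;
    std::vector<int> cof(5);
    for (int d = 0; d <= max_hom_dim; ++d) {
        const int k = d + 1; // vertices per d-simplex
        // columns of dim d in decreasing filtration order
        std::vector<uint32_t> cols_order;
        cols_order.reserve(F.vals[d].size());
        for (size_t p = n_tot; p-- > 0;)
            if (keys[order[p]].dim == d) cols_order.push_back(order[p]);
        // pivot row key -> stored reduced column (row keys ascending);
        // row key = n_tot - position, so the pivot (largest key) is the
        // cofacet earliest in the filtration
        std::vector<int32_t> owner(n_tot + 1, -1);
        std::vector<std::vector<int>> stored;
        std::vector<uint32_t> stored_src;
        for (uint32_t gidx : cols_order) {
            if (cleared[gidx]) continue; // already the death of a (d-1)-pair
            const Key& K = keys[gidx];
            const int* vtx = &F.verts[d][(size_t)K.id * k];
            rows.clear();
            for (int m = 0; m < N; ++m) {
                bool member = false;
                for (int i = 0; i < k; ++i)
                    if (vtx[i] == m) { member = true; break; }
                if (member) continue;
                int c = 0;
                bool placed = false;
                for (int i = 0; i < k; ++i) {
                    if (!placed && m < vtx[i]) { cof[c++] = m; placed = true; }
                    cof[c++] = vtx[i];
                }
                if (!placed) cof[c++] = m;
                int cid = lex_rank(cof.data(), k + 1, N, C);
                rows.push_back((int)(n_tot - pos[ncum[d + 1] + cid]));
            }
            std::sort(rows.begin(), rows.end());
            col.swap(rows);
            while (!col.empty()) {
                int piv = col.back();
                int32_t ow = owner[piv];
                if (ow < 0) break;
                symdiff(col, stored[ow], tmp);
                col.swap(tmp);
            }
            if (!col.empty()) {
                int piv = col.back();
                owner[piv] = (int32_t)stored.size();
                stored.push_back(col);
                stored_src.push_back(gidx);
                uint32_t death_gidx = order[n_tot - piv];
                cleared[death_gidx] = 1;
                double dv = keys[death_gidx].v;
                if (dv > K.v) { // zero-persistence pairs dropped
                    out_dim.push_back(d);
                    out_b.push_back(K.v);
                    out_d.push_back(dv);
                }
            } else {
                // essential class: survives to the end of the filtration
                out_dim.push_back(d);
                out_b.push_back(K.v);
                out_d.push_back(R_PosInf);
            }
        }
    }

    NumericMatrix out((int)out_dim.size(), 3);
    for (int i = 0; i < (int)out_dim.size(); ++i) {
        out(i, 0) = out_dim[i];
        out(i, 1) = out_b[i];
        out(i, 2) = out_d[i];
    }
    colnames(out) = CharacterVector::create("dimension", "birth", "death");
    return out;
}
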