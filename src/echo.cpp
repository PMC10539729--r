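// Coherent cluster propagation core.
//
// All Hamiltonians act on the nuclear spin space of one cluster of spin-1/2
// protons (dimension 2^n), conditional on the electron projection
// mS = +1/2 ("alpha") or -1/2 ("beta"); the electron Zeeman term is a
// constant within each block and is omitted.  Basis states are labelled by
// bit patterns, bit k set = spin k in mI = +1/2.
//
// Echo amplitudes are evaluated with the coherence-overlap trace formula
//   V = 2^-n Re Tr[ W_A W_B^H ]
// where W_A, W_B are the conditional propagators of the two coherence
// pathway branches.  U_x(t) = exp(-i H_x t) is obtained exactly from the
// eigendecomposition of the (small, Hermitian) blocks, so there is no time
// stepping error and arbitrary delay grids cost one diagonal phase each.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void build_hams(const std::vector<int>& idx,
                       const vec& Azz, const vec& Azx, const vec& Azy,
                       const mat& bmat, double omegaI,
                       cx_mat& Ha, cx_mat& Hb)
{
    const int n = (int) idx.size();
    const int d = 1 << n;
    Ha.zeros(d, d);
    Hb.zeros(d, d);
    for (int k = 0; k < n; ++k) {
        const int g = idx[k];
        const double azz = Azz(g);
        // <up| (Azx Ix + Azy Iy) |down> = Azx/2 - i Azy/2, times the 1/2
        // electron projection in H_{+/-}
        const cx_double off(0.25 * Azx(g), -0.25 * Azy(g));
        const int bk = 1 << k;
        for (int s = 0; s < d; ++s) {
            const double mz = (s & bk) ? 0.5 : -0.5;
            const double zee = -omegaI * mz;
            Ha(s, s) += zee + 0.5 * azz * mz;
            Hb(s, s) += zee - 0.5 * azz * mz;
            if (!(s & bk)) {
                const int s2 = s | bk;
                Ha(s2, s) += off;
                Ha(s, s2) += std::conj(off);
                Hb(s2, s) -= off;
                Hb(s, s2) -= std::conj(off);
            }
        }
    }
    for (int p = 0; p < n; ++p) {
        const int bp = 1 << p;
        for (int q = p + 1; q < n; ++q) {
            const double b = bmat(idx[p], idx[q]);
            if (b == 0.0) continue;
            const int bq = 1 << q;
            for (int s = 0; s < d; ++s) {
                const double mp = (s & bp) ? 0.5 : -0.5;
                const double mq = (s & bq) ? 0.5 : -0.5;
                const double dg = -4.0 * b * mp * mq;
                Ha(s, s) += dg;
                Hb(s, s) += dg;
                // flip-flop: |p up, q down> <-> |p down, q up>, element b
                if ((s & bp) && !(s & bq)) {
                    const int s2 = s ^ (bp | bq);
                    Ha(s2, s) += b;
                    Ha(s, s2) += b;
                    Hb(s2, s) += b;
                    Hb(s, s2) += b;
                }
            }
        }
    }
}

// V on the delay grid for one cluster; out has length n1 (Hahn) or n1*n2
// (refocused, tau1 fastest).
static void echo_points(const cx_mat& Ha, const cx_mat& Hb,
                        const vec& tau1, const vec& tau2, bool refocused,
                        double* out)
{
    const int d = (int) Ha.n_rows;
    vec la, lb;
    cx_mat Pa, Pb;
    eig_sym(la, Pa, Ha);
    eig_sym(lb, Pb, Hb);
    const cx_mat M  = Pa.t() * Pb;  // beta eigenbasis in alpha eigenbasis
    const cx_mat Mh = M.t();
    const cx_double i1(0.0, 1.0);
    const int n1 = (int) tau1.n_elem;

    if (!refocused) {
        // Tr[U_b(t) U_a(t) U_b(-t) U_a(-t)] in the alpha eigenbasis
        for (int i = 0; i < n1; ++i) {
            const cx_rowvec ea = exp(-i1 * la.t() * tau1(i));
            const cx_rowvec eb = exp(-i1 * lb.t() * tau1(i));
            cx_mat C = M;  C.each_row()  %= eb;
            const cx_mat Gb = C * Mh;
            cx_mat C2 = M; C2.each_row() %= conj(eb);
            const cx_mat Gbm = C2 * Mh;
            cx_mat Z = Gb;  Z.each_row() %= ea;
            cx_mat W = Gbm; W.each_row() %= conj(ea);
            out[i] = std::real(accu(Z % W.st())) / d;
        }
        return;
    }

    const int n2 = (int) tau2.n_elem;
    // caches over the two delay axes
    std::vector<cx_mat> G2(n1), G3(n2);
    std::vector<cx_rowvec> Ea1(n1), Eb1(n1), Ea2(n2), Eb2(n2);
    for (int i = 0; i < n1; ++i) {
        Ea1[i] = exp(-i1 * la.t() * tau1(i));
        Eb1[i] = exp(-i1 * lb.t() * tau1(i));
        cx_mat C = M; C.each_row() %= conj(Eb1[i]);
        G2[i] = C * Mh;                       // U_b(-tau1)
    }
    for (int j = 0; j < n2; ++j) {
        Ea2[j] = exp(-i1 * la.t() * tau2(j));
        Eb2[j] = exp(-i1 * lb.t() * tau2(j));
        cx_mat C = M; C.each_row() %= conj(Eb2[j]);
        G3[j] = C * Mh;                       // U_b(-tau2)
    }
    // Tr[E_a(t2) G1(t1+t2) E_a(t1) G2(t1) E_a(-t1-t2) G3(t2)],
    // G1(s) = U_b(s) in the alpha eigenbasis
    for (int j = 0; j < n2; ++j) {
        for (int i = 0; i < n1; ++i) {
            const cx_rowvec ebs = Eb1[i] % Eb2[j];
            const cx_rowvec eas = Ea1[i] % Ea2[j];
            cx_mat C = M; C.each_row() %= ebs;
            cx_mat G1 = C * Mh;
            G1.each_col() %= Ea2[j].st();     // diag(ea2) * G1
            G1.each_row() %= Ea1[i];          // ... * diag(ea1)
            cx_mat Z = G1 * G2[i];
            Z.each_row() %= conj(eas);
            out[i + (size_t) n1 * j] = std::real(accu(Z % G3[j].st())) / d;
        }
    }
}

// [[Rcpp::export]]
Rcpp::List cluster_hams_cpp(Rcpp::IntegerVector cluster,
                            arma::vec Azz, arma::vec Azx, arma::vec Azy,
                            arma::mat bmat, double omegaI)
{
    std::vector<int> idx(cluster.size());
    for (int i = 0; i < cluster.size(); ++i) idx[i] = cluster[i] - 1;
    cx_mat Ha, Hb;
    build_hams(idx, Azz, Azx, Azy, bmat, omegaI, Ha, Hb);
    return Rcpp::List::create(Rcpp::Named("H_alpha") = Ha,
                              Rcpp::Named("H_beta")  = Hb);
}

// [[Rcpp::export]]
arma::vec echo_signal_cpp(arma::cx_mat Ha, arma::cx_mat Hb,
                          arma::vec tau1, arma::vec tau2, bool refocused)
{
    const size_t npts = refocused ? tau1.n_elem * tau2.n_elem : tau1.n_elem;
    vec out(npts);
    echo_points(Ha, Hb, tau1, tau2, refocused, out.memptr());
    return out;
}

// Signals for a whole cluster list; returns npts x ncluster.
// [[Rcpp::export]]
arma::mat cce_signals_cpp(Rcpp::List clusters,
                          arma::vec Azz, arma::vec Azx, arma::vec Azy,
                          arma::mat bmat, double omegaI,
                          arma::vec tau1, arma::vec tau2, bool refocused)
{
    const size_t npts = refocused ? tau1.n_elem * tau2.n_elem : tau1.n_elem;
    const int nc = clusters.size();
    mat out(npts, nc);
    cx_mat Ha, Hb;
    for (int c = 0; c < nc; ++c) {
        Rcpp::IntegerVector cl = clusters[c];
        std::vector<int> idx(cl.size());
        for (int i = 0; i < cl.size(); ++i) idx[i] = cl[i] - 1;
        build_hams(idx, Azz, Azx, Azy, bmat, omegaI, Ha, Hb);
        echo_points(Ha, Hb, tau1, tau2, refocused, out.colptr(c));
    }
    return out;
}

// ---- connected-subset enumeration (ESU / Wernicke) ----
// Enumerates every connected vertex subset of size 2..kmax of the coupling
// graph exactly once.  Vertices and edges are 1-based on the R side.

struct EsuState {
    int kmax, v0;
    const std::vector<std::vector<int>>* adj;
    std::vector<int> sub;
    std::vector<char> seen;  // in sub, or already reachable via ext
    std::vector<std::vector<int>>* out;
};

static void esu_extend(EsuState& st, std::vector<int> ext)
{
    while (!ext.empty()) {
        const int w = ext.back();
        ext.pop_back();
        std::vector<int> ext2 = ext;
        std::vector<int> newly;
        for (int u : (*st.adj)[w]) {
            if (u > st.v0 && !st.seen[u]) {
                st.seen[u] = 1;
                newly.push_back(u);
                ext2.push_back(u);
            }
        }
        st.sub.push_back(w);
        if ((int) st.sub.size() >= 2) {
            std::vector<int> s = st.sub;
            std::sort(s.begin(), s.end());
            st.out->push_back(s);
        }
        if ((int) st.sub.size() < st.kmax) esu_extend(st, ext2);
        st.sub.pop_back();
        for (int u : newly) st.seen[u] = 0;
    }
}

// [[Rcpp::export]]
Rcpp::List connected_subsets_cpp(int n, Rcpp::IntegerVector ei,
                                 Rcpp::IntegerVector ej, int kmax)
{
    std::vector<std::vector<int>> adj(n);
    for (int e = 0; e < ei.size(); ++e) {
        adj[ei[e] - 1].push_back(ej[e] - 1);
        adj[ej[e] - 1].push_back(ei[e] - 1);
    }
    std::vector<std::vector<int>> found;
    EsuState st;
    st.kmax = kmax;
    st.adj = &adj;
    st.out = &found;
    st.seen.assign(n, 0);
    for (int v = 0; v < n; ++v) {
        st.v0 = v;
        st.seen[v] = 1;
        std::vector<int> ext;
        for (int u : adj[v]) if (u > v) { ext.push_back(u); st.seen[u] = 1; }
        std::vector<int> marked = ext;
        st.sub.assign(1, v);
        esu_extend(st, ext);
        st.seen[v] = 0;
        for (int u : marked) st.seen[u] = 0;
    }
    Rcpp::List res(found.size());
    for (size_t i = 0; i < found.size(); ++i) {
        Rcpp::IntegerVector v(found[i].size());
        for (size_t j = 0; j < found[i].size(); ++j) v[j] = found[i][j] + 1;
        res[i] = v;
    }
    return res;
}
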