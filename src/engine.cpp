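// Felsenstein pruning under a reversible 20-state model with discrete-gamma
// rate mixing. The tree arrives as an ape edge matrix in postorder; tip data
// as integer codes 1..20 (0 = gap/unknown -> all-ones partial vector).
//
// Besides the plain per-site log-likelihood, the engine exposes the cached
// conditional-likelihood arrays needed to re-evaluate the likelihood as a
// cheap 1-D function of a single branch length (for round-robin branch
// optimization) or of the central branch of an NNI quartet rearrangement.
// Transition matrices come from the model's symmetric eigendecomposition:
// P(t) = U diag(exp(lambda t)) Uinv.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NS = 20;

static inline void computeP(const double* U, const double* Uinv,
                            const double* lambda, double t, double* P) {
  double ev[NS];
  for (int m = 0; m < NS; ++m) ev[m] = std::exp(lambda[m] * t);
  for (int i = 0; i < NS; ++i) {
    for (int j = 0; j < NS; ++j) {
      double acc = 0.0;
      for (int m = 0; m < NS; ++m) acc += U[i + m * NS] * ev[m] * Uinv[m + j * NS];
      P[i * NS + j] = acc > 0.0 ? acc : 0.0;
    }
  }
}

struct Engine {
  int E, ntip, nint, S, K;
  const int* edge;      // E x 2, column-major, 1-based ape node ids
  const double* el;
  const int* tips;      // ntip x S, column-major
  const double* rates;
  const double* U, *Uinv, *lambda, *pi;

  Engine(const IntegerMatrix& edge_, const NumericVector& el_, int ntip_,
         int nnode_, const IntegerMatrix& tips_, const NumericVector& rates_,
         const NumericMatrix& U_, const NumericMatrix& Uinv_,
         const NumericVector& lambda_, const NumericVector& pi_)
    : E(edge_.nrow()), ntip(ntip_), nint(nnode_), S(tips_.ncol()),
      K(rates_.size()), edge(edge_.begin()), el(el_.begin()),
      tips(tips_.begin()), rates(rates_.begin()), U(U_.begin()),
      Uinv(Uinv_.begin()), lambda(lambda_.begin()), pi(pi_.begin()) {}

  inline int parent(int e) const { return edge[e] - 1; }
  inline int child(int e) const { return edge[e + E] - 1; }
  inline int iidx(int node) const { return node - ntip; } // internal index
  inline int tipstate(int tip, int s) const { return tips[tip + s * ntip]; }
};

// message through edge e toward the parent, for one category, all sites;
// down = internal-node conditionals (indexed by iidx), out gets S*NS values.
static void edge_message(const Engine& en, int e, int k,
                         const std::vector<double>& down,
                         const double* P, double* out) {
  int c = en.child(e);
  if (c < en.ntip) {
    for (int s = 0; s < en.S; ++s) {
      int st = en.tipstate(c, s);
      double* m = out + s * NS;
      if (st == 0) {
        for (int i = 0; i < NS; ++i) m[i] = 1.0;
      } else {
        for (int i = 0; i < NS; ++i) m[i] = P[i * NS + st - 1];
      }
    }
  } else {
    const double* d = down.data() +
      (static_cast<size_t>(en.iidx(c)) * en.K + k) * en.S * NS;
    for (int s = 0; s < en.S; ++s) {
      const double* dc = d + s * NS;
      double* m = out + s * NS;
      for (int i = 0; i < NS; ++i) {
        double acc = 0.0;
        const double* Pi = P + i * NS;
        for (int j = 0; j < NS; ++j) acc += Pi[j] * dc[j];
        m[i] = acc;
      }
    }
  }
}

// postorder pass: fills down (nint*K*S*NS) and dsc (nint*K*S log-scales)
static void postorder_pass(const Engine& en, std::vector<double>& down,
                           std::vector<double>& dsc) {
  size_t blk = static_cast<size_t>(en.S) * NS;
  down.assign(static_cast<size_t>(en.nint) * en.K * blk, 1.0);
  dsc.assign(static_cast<size_t>(en.nint) * en.K * en.S, 0.0);
  std::vector<double> P(NS * NS), m(blk);
  for (int e = 0; e < en.E; ++e) {
    int p = en.iidx(en.parent(e)), c = en.child(e);
    for (int k = 0; k < en.K; ++k) {
      computeP(en.U, en.Uinv, en.lambda, en.el[e] * en.rates[k], P.data());
      edge_message(en, e, k, down, P.data(), m.data());
      double* dp = down.data() + (static_cast<size_t>(p) * en.K + k) * blk;
      double* sp = dsc.data() + (static_cast<size_t>(p) * en.K + k) * en.S;
      const double* csc = (c >= en.ntip)
        ? dsc.data() + (static_cast<size_t>(en.iidx(c)) * en.K + k) * en.S
        : nullptr;
      for (int s = 0; s < en.S; ++s) {
        double* d = dp + s * NS;
        const double* mm = m.data() + s * NS;
        double mx = 0.0;
        for (int i = 0; i < NS; ++i) {
          d[i] *= mm[i];
          if (d[i] > mx) mx = d[i];
        }
        if (mx <= 0.0) stop("zero partial likelihood (site %d)", s + 1);
        for (int i = 0; i < NS; ++i) d[i] /= mx;
        sp[s] += std::log(mx) + (csc ? csc[s] : 0.0);
      }
    }
  }
}

static NumericVector root_site_loglik(const Engine& en,
                                      const std::vector<double>& down,
                                      const std::vector<double>& dsc) {
  NumericVector out(en.S);
  size_t blk = static_cast<size_t>(en.S) * NS;
  int r = 0; // root internal index (ape root = ntip + 1)
  for (int s = 0; s < en.S; ++s) {
    double best = R_NegInf;
    std::vector<double> vals(en.K);
    for (int k = 0; k < en.K; ++k) {
      const double* d = down.data() + (static_cast<size_t>(r) * en.K + k) * blk + s * NS;
      double lk = 0.0;
      for (int i = 0; i < NS; ++i) lk += en.pi[i] * d[i];
      vals[k] = std::log(lk) + dsc[(static_cast<size_t>(r) * en.K + k) * en.S + s];
      if (vals[k] > best) best = vals[k];
    }
    double acc = 0.0;
    for (int k = 0; k < en.K; ++k) acc += std::exp(vals[k] - best);
    out[s] = best + std::log(acc) - std::log(static_cast<double>(en.K));
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_site_loglik(IntegerMatrix edge, NumericVector el, int ntip,
                              int nnode, IntegerMatrix tips,
                              NumericVector rates, NumericMatrix U,
                              NumericMatrix Uinv, NumericVector lambda,
                              NumericVector pi) {
  Engine en(edge, el, ntip, nnode, tips, rates, U, Uinv, lambda, pi);
  std::vector<double> down, dsc;
  postorder_pass(en, down, dsc);
  return root_site_loglik(en, down, dsc);
}

// Full set of cached arrays: down/dsc per internal node, msg/msgsc per edge
// (message toward the parent), upe/upesc per edge (everything outside the
// child subtree, as a function of the state at the PARENT), and upn/upnsc per
// internal node (everything outside that node's subtree, as a function of the
// state at the node itself).
// [[Rcpp::export]]
List cpp_edge_arrays(IntegerMatrix edge, NumericVector el, int ntip, int nnode,
                     IntegerMatrix tips, NumericVector rates, NumericMatrix U,
                     NumericMatrix Uinv, NumericVector lambda,
                     NumericVector pi) {
  Engine en(edge, el, ntip, nnode, tips, rates, U, Uinv, lambda, pi);
  size_t blk = static_cast<size_t>(en.S) * NS;

  NumericVector msg(static_cast<R_xlen_t>(en.E) * en.K * blk);
  NumericVector msgsc(static_cast<R_xlen_t>(en.E) * en.K * en.S);
  NumericVector upe(static_cast<R_xlen_t>(en.E) * en.K * blk);
  NumericVector upesc(static_cast<R_xlen_t>(en.E) * en.K * en.S);
  NumericVector upn(static_cast<R_xlen_t>(en.nint) * en.K * blk, 1.0);
  NumericVector upnsc(static_cast<R_xlen_t>(en.nint) * en.K * en.S);

  // fused postorder: compute each edge's message once, store it (rescaled),
  // and multiply it into the parent's conditional
  std::vector<double> down(static_cast<size_t>(en.nint) * en.K * blk, 1.0);
  std::vector<double> dsc(static_cast<size_t>(en.nint) * en.K * en.S, 0.0);
  std::vector<double> P(NS * NS);
  for (int e = 0; e < en.E; ++e) {
    int p = en.iidx(en.parent(e)), c = en.child(e);
    for (int k = 0; k < en.K; ++k) {
      computeP(en.U, en.Uinv, en.lambda, en.el[e] * en.rates[k], P.data());
      double* m = msg.begin() + (static_cast<size_t>(e) * en.K + k) * blk;
      edge_message(en, e, k, down, P.data(), m);
      double* sc = msgsc.begin() + (static_cast<size_t>(e) * en.K + k) * en.S;
      const double* csc = (c >= en.ntip)
        ? dsc.data() + (static_cast<size_t>(en.iidx(c)) * en.K + k) * en.S
        : nullptr;
      double* dp = down.data() + (static_cast<size_t>(p) * en.K + k) * blk;
      double* sp = dsc.data() + (static_cast<size_t>(p) * en.K + k) * en.S;
      for (int s = 0; s < en.S; ++s) {
        double* mm = m + s * NS;
        double mx = 0.0;
        for (int i = 0; i < NS; ++i) if (mm[i] > mx) mx = mm[i];
        double* d = dp + s * NS;
        double dmx = 0.0;
        for (int i = 0; i < NS; ++i) {
          mm[i] /= mx;
          d[i] *= mm[i];
          if (d[i] > dmx) dmx = d[i];
        }
        if (dmx <= 0.0) stop("zero partial likelihood (site %d)", s + 1);
        for (int i = 0; i < NS; ++i) d[i] /= dmx;
        double msc = std::log(mx) + (csc ? csc[s] : 0.0);
        sc[s] = msc;
        sp[s] += msc + std::log(dmx);
      }
    }
  }

  // children edges of every internal node
  std::vector<std::vector<int>> kids(en.nint);
  for (int e = 0; e < en.E; ++e) kids[en.iidx(en.parent(e))].push_back(e);

  // preorder: upn[root] = 1; for edge f=(g,p): upe[f] = upn[g] * prod of
  // sibling msgs (function of state at g); upn[p] = P(t_f)^T-style push of
  // upe[f] down to p (reversible model: plain P(t_f) row action).
  for (int e = en.E - 1; e >= 0; --e) {
    int g = en.parent(e), c = en.child(e);
    int gi = en.iidx(g);
    for (int k = 0; k < en.K; ++k) {
      double* ue = upe.begin() + (static_cast<size_t>(e) * en.K + k) * blk;
      double* uesc = upesc.begin() + (static_cast<size_t>(e) * en.K + k) * en.S;
      const double* ug = upn.begin() + (static_cast<size_t>(gi) * en.K + k) * blk;
      const double* ugsc = upnsc.begin() + (static_cast<size_t>(gi) * en.K + k) * en.S;
      for (int s = 0; s < en.S; ++s) {
        double* u = ue + s * NS;
        const double* gsrc = ug + s * NS;
        for (int i = 0; i < NS; ++i) u[i] = gsrc[i];
        uesc[s] = ugsc[s];
      }
      for (int sib : kids[gi]) {
        if (sib == e) continue;
        const double* sm = msg.begin() + (static_cast<size_t>(sib) * en.K + k) * blk;
        const double* ssc = msgsc.begin() + (static_cast<size_t>(sib) * en.K + k) * en.S;
        for (int s = 0; s < en.S; ++s) {
          double* u = ue + s * NS;
          const double* mm = sm + s * NS;
          for (int i = 0; i < NS; ++i) u[i] *= mm[i];
          uesc[s] += ssc[s];
        }
      }
      for (int s = 0; s < en.S; ++s) { // rescale
        double* u = ue + s * NS;
        double mx = 0.0;
        for (int i = 0; i < NS; ++i) if (u[i] > mx) mx = u[i];
        for (int i = 0; i < NS; ++i) u[i] /= mx;
        uesc[s] += std::log(mx);
      }
      if (c >= en.ntip) { // push through edge e to get upn[child]
        computeP(en.U, en.Uinv, en.lambda, en.el[e] * en.rates[k], P.data());
        int ci = en.iidx(c);
        double* uc = upn.begin() + (static_cast<size_t>(ci) * en.K + k) * blk;
        double* ucsc = upnsc.begin() + (static_cast<size_t>(ci) * en.K + k) * en.S;
        for (int s = 0; s < en.S; ++s) {
          const double* u = ue + s * NS;
          double* t = uc + s * NS;
          double mx = 0.0;
          for (int i = 0; i < NS; ++i) {
            double acc = 0.0;
            const double* Pi = P.data() + i * NS;
            for (int j = 0; j < NS; ++j) acc += Pi[j] * u[j];
            t[i] = acc;
            if (acc > mx) mx = acc;
          }
          for (int i = 0; i < NS; ++i) t[i] /= mx;
          ucsc[s] = uesc[s] + std::log(mx);
        }
      }
    }
  }

  return List::create(
    _["down"] = NumericVector(down.begin(), down.end()),
    _["dsc"] = NumericVector(dsc.begin(), dsc.end()),
    _["msg"] = msg, _["msgsc"] = msgsc,
    _["upe"] = upe, _["upesc"] = upesc,
    _["upn"] = upn, _["upnsc"] = upnsc);
}

// total log-likelihood as a function of one branch length t for edge e
// (0-based row of the edge matrix), using cached arrays; sites carry
// pattern weights w.
// [[Rcpp::export]]
double cpp_edge_loglik(int e, double t, IntegerMatrix edge, int ntip,
                       int nnode, IntegerMatrix tips, NumericVector rates,
                       NumericMatrix U, NumericMatrix Uinv,
                       NumericVector lambda, NumericVector pi,
                       NumericVector down, NumericVector dsc,
                       NumericVector upe, NumericVector upesc,
                       NumericVector w) {
  NumericVector el(edge.nrow()); // lengths unused on this path
  Engine en(edge, el, ntip, nnode, tips, rates, U, Uinv, lambda, pi);
  size_t blk = static_cast<size_t>(en.S) * NS;
  int c = en.child(e);
  std::vector<double> P(NS * NS);
  std::vector<double> vals(en.K);
  double total = 0.0;
  std::vector<std::vector<double>> Pk(en.K, std::vector<double>(NS * NS));
  for (int k = 0; k < en.K; ++k)
    computeP(en.U, en.Uinv, en.lambda, t * en.rates[k], Pk[k].data());
  for (int s = 0; s < en.S; ++s) {
    double best = R_NegInf;
    for (int k = 0; k < en.K; ++k) {
      const double* u = upe.begin() + (static_cast<size_t>(e) * en.K + k) * blk + s * NS;
      double usc = upesc[(static_cast<size_t>(e) * en.K + k) * en.S + s];
      double lk = 0.0, csc = 0.0;
      if (c < en.ntip) {
        int st = en.tipstate(c, s);
        if (st == 0) {
          for (int i = 0; i < NS; ++i) lk += en.pi[i] * u[i];
        } else {
          const double* Pm = Pk[k].data();
          for (int i = 0; i < NS; ++i) lk += en.pi[i] * u[i] * Pm[i * NS + st - 1];
        }
      } else {
        int ci = en.iidx(c);
        const double* d = down.begin() + (static_cast<size_t>(ci) * en.K + k) * blk + s * NS;
        csc = dsc[(static_cast<size_t>(ci) * en.K + k) * en.S + s];
        const double* Pm = Pk[k].data();
        for (int i = 0; i < NS; ++i) {
          double acc = 0.0;
          const double* Pi = Pm + i * NS;
          for (int j = 0; j < NS; ++j) acc += Pi[j] * d[j];
          lk += en.pi[i] * u[i] * acc;
        }
      }
      vals[k] = std::log(lk) + usc + csc;
      if (vals[k] > best) best = vals[k];
    }
    double acc = 0.0;
    for (int k = 0; k < en.K; ++k) acc += std::exp(vals[k] - best);
    total += w[s] * (best + std::log(acc) -
                     std::log(static_cast<double>(en.K)));
  }
  return total;
}

// log-likelihood of a quartet arrangement around a central edge of length t:
// units a1,a2 sit at one endpoint, b1,b2 at the other. A unit is either the
// message of an edge (type 0, index = edge row) or the outside-subtree array
// of an internal node (type 1, index = internal node index, i.e. ape node -
// ntip - 1). Used to score NNI rearrangements without touching the tree.
// [[Rcpp::export]]
double cpp_quartet_loglik(double t, IntegerVector unit_type,
                          IntegerVector unit_idx, int ntip, int nnode, int S,
                          NumericVector rates, NumericMatrix U,
                          NumericMatrix Uinv, NumericVector lambda,
                          NumericVector pi, NumericVector msg,
                          NumericVector msgsc, NumericVector upn,
                          NumericVector upnsc, NumericVector w) {
  int K = rates.size();
  size_t blk = static_cast<size_t>(S) * NS;
  std::vector<const double*> arr(4);
  std::vector<const double*> asc(4);
  std::vector<std::vector<double>> Pk(K, std::vector<double>(NS * NS));
  for (int k = 0; k < K; ++k)
    computeP(U.begin(), Uinv.begin(), lambda.begin(), t * rates[k], Pk[k].data());
  double total = 0.0;
  std::vector<double> vals(K);
  for (int s = 0; s < S; ++s) {
    double best = R_NegInf;
    for (int k = 0; k < K; ++k) {
      for (int u = 0; u < 4; ++u) {
        const NumericVector& src = unit_type[u] == 0 ? msg : upn;
        const NumericVector& ssc = unit_type[u] == 0 ? msgsc : upnsc;
        arr[u] = src.begin() + (static_cast<size_t>(unit_idx[u]) * K + k) * blk + s * NS;
        asc[u] = ssc.begin() + (static_cast<size_t>(unit_idx[u]) * K + k) * S + s;
      }
      double left[NS], right[NS];
      for (int i = 0; i < NS; ++i) {
        left[i] = arr[0][i] * arr[1][i];
        right[i] = arr[2][i] * arr[3][i];
      }
      const double* Pm = Pk[k].data();
      double lk = 0.0;
      for (int i = 0; i < NS; ++i) {
        double acc = 0.0;
        const double* Pi = Pm + i * NS;
        for (int j = 0; j < NS; ++j) acc += Pi[j] * right[j];
        lk += pi[i] * left[i] * acc;
      }
      vals[k] = std::log(lk) + *asc[0] + *asc[1] + *asc[2] + *asc[3];
      if (vals[k] > best) best = vals[k];
    }
    double acc = 0.0;
    for (int k = 0; k < K; ++k) acc += std::exp(vals[k] - best);
    total += w[s] * (best + std::log(acc) - std::log(static_cast<double>(K)));
  }
  return total;
}
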