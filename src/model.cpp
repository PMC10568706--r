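// Numeric core of the graph-convolutional fragment generator.
//
// Layout of the parameter list (all arma::mat, biases as 1 x k rows):
//   enc_W0_l, enc_W1_l, enc_W2_l, enc_W3_l, enc_b_l   l = 1..L
//     (W0 = self term; W1..W3 = per-bond-order message weights.
//      flavor "gcn" uses only W1 on the order-agnostic adjacency.)
//   atom_W1, atom_b1, atom_W2, atom_b2                atom head MLP
//   emb                                               element embedding
//   init_W, init_b                                    GRU state init
//   gru1_Wx, gru1_Wh, gru1_bx, gru1_bh                GRU layer 1
//   gru2_Wx, gru2_Wh, gru2_bx, gru2_bh                GRU layer 2
//   bond_W1, bond_b1, bond_W2, bond_b2                bond output MLP
// Gate layout inside the 3S-wide GRU matrices: [ r | z | n ].
// Update rule (torch convention): h' = (1 - z) % n + z % h.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Cfg {
  int L;            // encoder layers
  bool edge_typed;  // true = per-bond-order messages, false = plain GCN
  int n_elements;   // real atom classes (stop label = n_elements + 1)
};

Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.L = as<int>(cfg["mpnn_layers"]);
  std::string flavor = as<std::string>(cfg["flavor"]);
  c.edge_typed = (flavor == "mpnn");
  c.n_elements = as<int>(cfg["n_elements"]);
  return c;
}

// no-copy view into an R matrix held by the parameter list; relies on
// guaranteed copy elision, and on the List outliving the view (true for
// every call below — the list is an argument of the exported function)
arma::mat getm(const List& p, const std::string& name) {
  NumericMatrix m = p[name];
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}

inline arma::rowvec softmax_row(const arma::rowvec& x) {
  arma::rowvec e = arma::exp(x - x.max());
  return e / arma::accu(e);
}

inline arma::mat relu(const arma::mat& x) { return arma::clamp(x, 0.0, arma::datum::inf); }

// symmetric-degree-normalized adjacency, one matrix per bond order
// (plus the pooled one used by the plain-GCN flavor)
void build_adjacency(int n, const arma::imat& bonds, bool edge_typed,
                     std::vector<arma::mat>& A) {
  arma::vec deg(n, arma::fill::zeros);
  for (arma::uword r = 0; r < bonds.n_rows; ++r) {
    deg(bonds(r, 0) - 1) += 1.0;
    deg(bonds(r, 1) - 1) += 1.0;
  }
  int nmat = edge_typed ? 3 : 1;
  A.assign(nmat, arma::mat(n, n, arma::fill::zeros));
  for (arma::uword r = 0; r < bonds.n_rows; ++r) {
    int i = bonds(r, 0) - 1, j = bonds(r, 1) - 1;
    int o = bonds(r, 2);
    double w = 1.0 / std::sqrt(deg(i) * deg(j));
    int slot = edge_typed ? (o - 1) : 0;
    A[slot](i, j) = w;
    A[slot](j, i) = w;
  }
}

struct EncCache {
  std::vector<arma::mat> H;   // H[0] = X, H[l] post-activation
  std::vector<arma::mat> A;   // normalized adjacencies
  arma::rowvec hg;
};

struct ParamSet {
  const List& p;
  Cfg c;
  ParamSet(const List& p_, const Cfg& c_) : p(p_), c(c_) {}
  arma::mat operator()(const std::string& n) const { return getm(p, n); }
};

void encode_forward(const ParamSet& P, const arma::ivec& atoms,
                    const arma::imat& bonds, EncCache& ec) {
  int n = atoms.n_elem;
  arma::mat X(n, P.c.n_elements, arma::fill::zeros);
  for (int i = 0; i < n; ++i) X(i, atoms(i) - 1) = 1.0;
  build_adjacency(n, bonds, P.c.edge_typed, ec.A);
  ec.H.assign(P.c.L + 1, arma::mat());
  ec.H[0] = X;
  for (int l = 1; l <= P.c.L; ++l) {
    std::string sl = std::to_string(l);
    arma::mat Z = ec.H[l - 1] * P("enc_W0_" + sl);
    for (size_t b = 0; b < ec.A.size(); ++b) {
      Z += ec.A[b] * (ec.H[l - 1] * P("enc_W" + std::to_string(b + 1) + "_" + sl));
    }
    Z.each_row() += arma::rowvec(P("enc_b_" + sl));
    ec.H[l] = relu(Z);
  }
  ec.hg = arma::sum(ec.H[P.c.L], 0);
}

// caches for one GRU layer across the bond sequence
struct GruCache {
  std::vector<arma::rowvec> h_prev, r, z, nn, ghn; // ghn = h_prev*Whn + bhn
  std::vector<arma::rowvec> h_out;
};

void gru_step(const arma::rowvec& x, const arma::rowvec& h,
              const arma::mat& Wx, const arma::mat& Wh,
              const arma::rowvec& bx, const arma::rowvec& bh,
              int S, GruCache& gc) {
  arma::rowvec gx = x * Wx + bx;
  arma::rowvec gh = h * Wh + bh;
  arma::rowvec r = 1.0 / (1.0 + arma::exp(-(gx.cols(0, S - 1) + gh.cols(0, S - 1))));
  arma::rowvec z = 1.0 / (1.0 + arma::exp(-(gx.cols(S, 2 * S - 1) + gh.cols(S, 2 * S - 1))));
  arma::rowvec ghn = gh.cols(2 * S, 3 * S - 1);
  arma::rowvec nn = arma::tanh(gx.cols(2 * S, 3 * S - 1) + r % ghn);
  arma::rowvec hout = (1.0 - z) % nn + z % h;
  gc.h_prev.push_back(h);
  gc.r.push_back(r);
  gc.z.push_back(z);
  gc.nn.push_back(nn);
  gc.ghn.push_back(ghn);
  gc.h_out.push_back(hout);
}

// backward through one GRU step; returns dx, updates dh carry, accumulates
// parameter grads
arma::rowvec gru_back(const GruCache& gc, size_t t, const arma::rowvec& x,
                      const arma::rowvec& dh_out,
                      const arma::mat& Wx, const arma::mat& Wh,
                      arma::mat& dWx, arma::mat& dWh,
                      arma::rowvec& dbx, arma::rowvec& dbh,
                      arma::rowvec& dh_prev_out, int S) {
  const arma::rowvec& h = gc.h_prev[t];
  const arma::rowvec& r = gc.r[t];
  const arma::rowvec& z = gc.z[t];
  const arma::rowvec& nn = gc.nn[t];
  const arma::rowvec& ghn = gc.ghn[t];
  arma::rowvec dz = dh_out % (h - nn);
  arma::rowvec dnn = dh_out % (1.0 - z);
  arma::rowvec dh_direct = dh_out % z;
  arma::rowvec dnn_pre = dnn % (1.0 - nn % nn);
  arma::rowvec dr = dnn_pre % ghn;
  arma::rowvec dghn = dnn_pre % r;
  arma::rowvec dz_pre = dz % z % (1.0 - z);
  arma::rowvec dr_pre = dr % r % (1.0 - r);
  arma::rowvec dgx = arma::join_rows(arma::join_rows(dr_pre, dz_pre), dnn_pre);
  arma::rowvec dgh = arma::join_rows(arma::join_rows(dr_pre, dz_pre), dghn);
  dWx += x.t() * dgx;
  dbx += dgx;
  dWh += h.t() * dgh;
  dbh += dgh;
  dh_prev_out = dh_direct + dgh * Wh.t();
  return dgx * Wx.t();
}

void zero_like(const List& params, List& grads) {
  CharacterVector nm = params.names();
  for (int i = 0; i < nm.size(); ++i) {
    arma::mat m = getm(params, as<std::string>(nm[i]));
    grads[as<std::string>(nm[i])] =
        arma::mat(m.n_rows, m.n_cols, arma::fill::zeros);
  }
}

void add_to(List& grads, const std::string& name, const arma::mat& g) {
  arma::mat cur = as<arma::mat>(grads[name]);
  grads[name] = cur + g;
}

} // namespace

// Forward + (optionally) backward over a batch of teacher-forcing steps.
// Returns total loss, per-head losses, and summed gradients.
// [[Rcpp::export]]
List mt_batch_grad(List params, List steps, List cfg, bool grad = true) {
  Cfg c = read_cfg(cfg);
  ParamSet P(params, c);
  int S = getm(params, "gru1_Wh").n_rows;
  int E = getm(params, "emb").n_cols;
  int stop_label = c.n_elements + 1;

  List grads;
  if (grad) zero_like(params, grads);

  // pull the frequently used matrices once
  arma::mat atom_W1 = P("atom_W1"), atom_W2 = P("atom_W2");
  arma::rowvec atom_b1 = arma::rowvec(P("atom_b1"));
  arma::rowvec atom_b2 = arma::rowvec(P("atom_b2"));
  arma::mat emb = P("emb");
  arma::mat init_W = P("init_W");
  arma::rowvec init_b = arma::rowvec(P("init_b"));
  arma::mat g1Wx = P("gru1_Wx"), g1Wh = P("gru1_Wh");
  arma::rowvec g1bx = arma::rowvec(P("gru1_bx")), g1bh = arma::rowvec(P("gru1_bh"));
  arma::mat g2Wx = P("gru2_Wx"), g2Wh = P("gru2_Wh");
  arma::rowvec g2bx = arma::rowvec(P("gru2_bx")), g2bh = arma::rowvec(P("gru2_bh"));
  arma::mat bond_W1 = P("bond_W1"), bond_W2 = P("bond_W2");
  arma::rowvec bond_b1 = arma::rowvec(P("bond_b1"));
  arma::rowvec bond_b2 = arma::rowvec(P("bond_b2"));
  int D = atom_W1.n_rows;

  double loss_total = 0.0, loss_atom = 0.0, loss_bond = 0.0;
  int n_bond_terms = 0;

  // encoder grad accumulators
  arma::mat d_atom_W1(atom_W1.n_rows, atom_W1.n_cols, arma::fill::zeros);
  arma::rowvec d_atom_b1(atom_b1.n_elem, arma::fill::zeros);
  arma::mat d_atom_W2(atom_W2.n_rows, atom_W2.n_cols, arma::fill::zeros);
  arma::rowvec d_atom_b2(atom_b2.n_elem, arma::fill::zeros);
  arma::mat d_emb(emb.n_rows, emb.n_cols, arma::fill::zeros);
  arma::mat d_init_W(init_W.n_rows, init_W.n_cols, arma::fill::zeros);
  arma::rowvec d_init_b(init_b.n_elem, arma::fill::zeros);
  arma::mat d_g1Wx(g1Wx.n_rows, g1Wx.n_cols, arma::fill::zeros), d_g1Wh(g1Wh.n_rows, g1Wh.n_cols, arma::fill::zeros);
  arma::rowvec d_g1bx(g1bx.n_elem, arma::fill::zeros), d_g1bh(g1bh.n_elem, arma::fill::zeros);
  arma::mat d_g2Wx(g2Wx.n_rows, g2Wx.n_cols, arma::fill::zeros), d_g2Wh(g2Wh.n_rows, g2Wh.n_cols, arma::fill::zeros);
  arma::rowvec d_g2bx(g2bx.n_elem, arma::fill::zeros), d_g2bh(g2bh.n_elem, arma::fill::zeros);
  arma::mat d_bond_W1(bond_W1.n_rows, bond_W1.n_cols, arma::fill::zeros);
  arma::rowvec d_bond_b1(bond_b1.n_elem, arma::fill::zeros);
  arma::mat d_bond_W2(bond_W2.n_rows, bond_W2.n_cols, arma::fill::zeros);
  arma::rowvec d_bond_b2(bond_b2.n_elem, arma::fill::zeros);

  int nW = c.edge_typed ? 3 : 1;
  std::vector<std::vector<arma::mat> > d_encW(c.L + 1);
  std::vector<arma::rowvec> d_encb(c.L + 1);
  std::vector<std::vector<arma::mat> > encW(c.L + 1);
  std::vector<arma::rowvec> encb(c.L + 1);
  for (int l = 1; l <= c.L; ++l) {
    std::string sl = std::to_string(l);
    encW[l].resize(nW + 1);
    d_encW[l].resize(nW + 1);
    for (int b = 0; b <= nW; ++b) {
      encW[l][b] = P("enc_W" + std::to_string(b) + "_" + sl);
      d_encW[l][b] = arma::mat(encW[l][b].n_rows, encW[l][b].n_cols,
                               arma::fill::zeros);
    }
    encb[l] = arma::rowvec(P("enc_b_" + sl));
    d_encb[l] = arma::rowvec(encb[l].n_elem, arma::fill::zeros);
  }

  for (int s = 0; s < steps.size(); ++s) {
    List st = steps[s];
    arma::ivec atoms = as<arma::ivec>(st["atoms"]);
    arma::imat bonds;
    {
      IntegerMatrix bm = st["bonds"];
      bonds.set_size(bm.nrow(), 3);
      for (int r = 0; r < bm.nrow(); ++r)
        for (int cc = 0; cc < 3; ++cc) bonds(r, cc) = bm(r, cc);
    }
    int ya = as<int>(st["atom_label"]);
    arma::ivec yb = as<arma::ivec>(st["bond_labels"]);
    int n = atoms.n_elem;

    // ---------- forward ----------
    EncCache ec;
    arma::rowvec hg(D, arma::fill::zeros);
    if (n > 0) {
      encode_forward(P, atoms, bonds, ec);
      hg = ec.hg;
    }
    arma::rowvec u1 = relu(hg * atom_W1 + atom_b1);
    arma::rowvec alog = u1 * atom_W2 + atom_b2;
    arma::rowvec pa = softmax_row(alog);
    double la = -std::log(std::max(pa(ya - 1), 1e-12));
    loss_atom += la;
    loss_total += la;

    bool do_bonds = (ya != stop_label) && (n > 0);
    GruCache gc1, gc2;
    std::vector<arma::rowvec> o1s, pbs;
    arma::rowvec s0;
    arma::rowvec cvec;
    if (do_bonds) {
      arma::rowvec e = emb.row(ya - 1);
      cvec = arma::join_rows(e, hg);
      s0 = arma::tanh(cvec * init_W + init_b);
      arma::rowvec s1 = s0.cols(0, S - 1);
      arma::rowvec s2 = s0.cols(S, 2 * S - 1);
      for (int t = 0; t < n; ++t) {
        arma::rowvec x = ec.H[c.L].row(t);
        gru_step(x, s1, g1Wx, g1Wh, g1bx, g1bh, S, gc1);
        s1 = gc1.h_out[t];
        gru_step(s1, s2, g2Wx, g2Wh, g2bx, g2bh, S, gc2);
        s2 = gc2.h_out[t];
        arma::rowvec o1 = relu(s2 * bond_W1 + bond_b1);
        arma::rowvec blog = o1 * bond_W2 + bond_b2;
        arma::rowvec pb = softmax_row(blog);
        o1s.push_back(o1);
        pbs.push_back(pb);
        double lb = -std::log(std::max(pb(yb(t) - 1), 1e-12));
        loss_bond += lb;
        loss_total += lb;
        ++n_bond_terms;
      }
    }

    if (!grad) continue;

    // ---------- backward ----------
    arma::rowvec dhg(D, arma::fill::zeros);
    arma::mat dHL;
    if (n > 0) dHL = arma::mat(n, D, arma::fill::zeros);

    // atom head
    arma::rowvec dalog = pa;
    dalog(ya - 1) -= 1.0;
    d_atom_W2 += u1.t() * dalog;
    d_atom_b2 += dalog;
    arma::rowvec du1 = dalog * atom_W2.t();
    du1 = du1 % arma::conv_to<arma::rowvec>::from(u1 > 0);
    d_atom_W1 += hg.t() * du1;
    d_atom_b1 += du1;
    dhg += du1 * atom_W1.t();

    if (do_bonds) {
      arma::rowvec carry1(S, arma::fill::zeros), carry2(S, arma::fill::zeros);
      for (int t = n - 1; t >= 0; --t) {
        // bond output head at t
        arma::rowvec dblog = pbs[t];
        dblog(yb(t) - 1) -= 1.0;
        d_bond_W2 += o1s[t].t() * dblog;
        d_bond_b2 += dblog;
        arma::rowvec do1 = dblog * bond_W2.t();
        do1 = do1 % arma::conv_to<arma::rowvec>::from(o1s[t] > 0);
        d_bond_W1 += gc2.h_out[t].t() * do1;
        d_bond_b1 += do1;
        arma::rowvec ds2 = carry2 + do1 * bond_W1.t();
        // layer 2: input was gc1.h_out[t]
        arma::rowvec dh_prev2;
        arma::rowvec dx2 = gru_back(gc2, t, gc1.h_out[t], ds2, g2Wx, g2Wh,
                                    d_g2Wx, d_g2Wh, d_g2bx, d_g2bh,
                                    dh_prev2, S);
        carry2 = dh_prev2;
        // layer 1: input was H_L row t
        arma::rowvec ds1 = carry1 + dx2;
        arma::rowvec dh_prev1;
        arma::rowvec x = ec.H[c.L].row(t);
        arma::rowvec dx = gru_back(gc1, t, x, ds1, g1Wx, g1Wh,
                                   d_g1Wx, d_g1Wh, d_g1bx, d_g1bh,
                                   dh_prev1, S);
        carry1 = dh_prev1;
        dHL.row(t) += dx;
      }
      // initial state
      arma::rowvec ds0 = arma::join_rows(carry1, carry2);
      ds0 = ds0 % (1.0 - s0 % s0);
      d_init_W += cvec.t() * ds0;
      d_init_b += ds0;
      arma::rowvec dc = ds0 * init_W.t();
      d_emb.row(ya - 1) += dc.cols(0, E - 1);
      dhg += dc.cols(E, E + D - 1);
    }

    // encoder
    if (n > 0) {
      dHL.each_row() += dhg; // sum pooling
      arma::mat dH = dHL;
      for (int l = c.L; l >= 1; --l) {
        arma::mat dZ = dH % arma::conv_to<arma::mat>::from(ec.H[l] > 0);
        d_encb[l] += arma::sum(dZ, 0);
        const arma::mat& Hin = ec.H[l - 1];
        d_encW[l][0] += Hin.t() * dZ;
        arma::mat dHin = dZ * encW[l][0].t();
        for (int b = 1; b <= nW; ++b) {
          arma::mat AH = ec.A[b - 1] * Hin;
          d_encW[l][b] += AH.t() * dZ;
          // A is symmetric, so A^T = A
          dHin += ec.A[b - 1] * (dZ * encW[l][b].t());
        }
        dH = dHin;
      }
    }
  }

  List out;
  out["loss"] = loss_total;
  out["loss_atom"] = loss_atom;
  out["loss_bond"] = loss_bond;
  out["n_steps"] = steps.size();
  out["n_bond_terms"] = n_bond_terms;
  if (grad) {
    grads["atom_W1"] = d_atom_W1; grads["atom_b1"] = arma::mat(d_atom_b1);
    grads["atom_W2"] = d_atom_W2; grads["atom_b2"] = arma::mat(d_atom_b2);
    grads["emb"] = d_emb;
    grads["init_W"] = d_init_W; grads["init_b"] = arma::mat(d_init_b);
    grads["gru1_Wx"] = d_g1Wx; grads["gru1_Wh"] = d_g1Wh;
    grads["gru1_bx"] = arma::mat(d_g1bx); grads["gru1_bh"] = arma::mat(d_g1bh);
    grads["gru2_Wx"] = d_g2Wx; grads["gru2_Wh"] = d_g2Wh;
    grads["gru2_bx"] = arma::mat(d_g2bx); grads["gru2_bh"] = arma::mat(d_g2bh);
    grads["bond_W1"] = d_bond_W1; grads["bond_b1"] = arma::mat(d_bond_b1);
    grads["bond_W2"] = d_bond_W2; grads["bond_b2"] = arma::mat(d_bond_b2);
    for (int l = 1; l <= c.L; ++l) {
      std::string sl = std::to_string(l);
      for (int b = 0; b <= nW; ++b)
        grads["enc_W" + std::to_string(b) + "_" + sl] = d_encW[l][b];
      grads["enc_b_" + sl] = arma::mat(d_encb[l]);
    }
    out["grads"] = grads;
  }
  return out;
}

// Node and graph hidden states for one molecular graph.
// [[Rcpp::export]]
List mt_encode(List params, IntegerVector atoms, IntegerMatrix bonds,
               List cfg) {
  Cfg c = read_cfg(cfg);
  ParamSet P(params, c);
  arma::ivec av = as<arma::ivec>(atoms);
  arma::imat bm(bonds.nrow(), 3);
  for (int r = 0; r < bonds.nrow(); ++r)
    for (int cc = 0; cc < 3; ++cc) bm(r, cc) = bonds(r, cc);
  EncCache ec;
  encode_forward(P, av, bm, ec);
  return List::create(_["h_n"] = ec.H[c.L], _["h_g"] = ec.hg);
}

// Probability vector over the 10 atom labels.
// [[Rcpp::export]]
arma::rowvec mt_atom_probs(List params, arma::rowvec hg) {
  arma::mat W1 = getm(params, "atom_W1"), W2 = getm(params, "atom_W2");
  arma::rowvec b1 = arma::rowvec(getm(params, "atom_b1"));
  arma::rowvec b2 = arma::rowvec(getm(params, "atom_b2"));
  arma::rowvec u1 = relu(hg * W1 + b1);
  return softmax_row(u1 * W2 + b2);
}

namespace {

struct BondHead {
  arma::mat emb, init_W, g1Wx, g1Wh, g2Wx, g2Wh, bond_W1, bond_W2;
  arma::rowvec init_b, g1bx, g1bh, g2bx, g2bh, bond_b1, bond_b2;
  int S;
  // initializer list so the no-copy views from getm() are kept as views
  explicit BondHead(const List& params)
      : emb(getm(params, "emb")),
        init_W(getm(params, "init_W")),
        g1Wx(getm(params, "gru1_Wx")), g1Wh(getm(params, "gru1_Wh")),
        g2Wx(getm(params, "gru2_Wx")), g2Wh(getm(params, "gru2_Wh")),
        bond_W1(getm(params, "bond_W1")), bond_W2(getm(params, "bond_W2")),
        init_b(getm(params, "init_b")),
        g1bx(getm(params, "gru1_bx")), g1bh(getm(params, "gru1_bh")),
        g2bx(getm(params, "gru2_bx")), g2bh(getm(params, "gru2_bh")),
        bond_b1(getm(params, "bond_b1")), bond_b2(getm(params, "bond_b2")),
        S(g1Wh.n_rows) {}
  void init_states(const arma::rowvec& hg, int atom_label,
                   arma::rowvec& s1, arma::rowvec& s2) const {
    arma::rowvec c = arma::join_rows(emb.row(atom_label - 1), hg);
    arma::rowvec s0 = arma::tanh(c * init_W + init_b);
    s1 = s0.cols(0, S - 1);
    s2 = s0.cols(S, 2 * S - 1);
  }
  arma::rowvec step(const arma::rowvec& x, arma::rowvec& s1,
                    arma::rowvec& s2) const {
    GruCache gc1, gc2;
    gru_step(x, s1, g1Wx, g1Wh, g1bx, g1bh, S, gc1);
    s1 = gc1.h_out[0];
    gru_step(s1, s2, g2Wx, g2Wh, g2bx, g2bh, S, gc2);
    s2 = gc2.h_out[0];
    arma::rowvec o1 = relu(s2 * bond_W1 + bond_b1);
    return softmax_row(o1 * bond_W2 + bond_b2);
  }
};

} // namespace

// Unmasked bond probabilities for each existing atom (teacher forcing /
// inspection). Rows of Hn must be in BFS order.
// [[Rcpp::export]]
arma::mat mt_bond_probs(List params, arma::mat Hn, arma::rowvec hg,
                        int atom_label) {
  BondHead B(params);
  int n = Hn.n_rows;
  arma::mat out(n, 4);
  arma::rowvec s1, s2;
  B.init_states(hg, atom_label, s1, s2);
  for (int t = 0; t < n; ++t)
    out.row(t) = B.step(Hn.row(t), s1, s2);
  return out;
}

// Valence-masked sequential bond sampling. free_val: free valence of each
// existing atom (in row order of Hn); new_cap: free valence budget of the
// incoming atom. unifs: one U(0,1) draw per existing atom (ignored when
// greedy). Returns 1-based labels (4 = none) and the joint probability of
// the chosen sequence under the masked distributions.
// [[Rcpp::export]]
List mt_sample_bonds(List params, arma::mat Hn, arma::rowvec hg,
                     int atom_label, IntegerVector free_val, int new_cap,
                     NumericVector unifs, bool greedy) {
  BondHead B(params);
  int n = Hn.n_rows;
  IntegerVector labels(n);
  double joint = 1.0;
  int rem = new_cap;
  arma::rowvec s1, s2;
  B.init_states(hg, atom_label, s1, s2);
  for (int t = 0; t < n; ++t) {
    arma::rowvec p = B.step(Hn.row(t), s1, s2);
    // mask orders that exceed either endpoint's remaining valence
    for (int o = 1; o <= 3; ++o)
      if (o > free_val[t] || o > rem) p(o - 1) = 0.0;
    double tot = arma::accu(p);
    if (tot <= 0) { // only "none" possible
      p.zeros(); p(3) = 1.0; tot = 1.0;
    }
    p /= tot;
    int pick = 3;
    if (greedy) {
      pick = p.index_max();
    } else {
      double u = unifs[t], acc = 0.0;
      for (int k = 0; k < 4; ++k) {
        acc += p(k);
        if (u <= acc) { pick = k; break; }
      }
    }
    labels[t] = pick + 1;
    joint *= p(pick);
    if (pick < 3) rem -= (pick + 1);
  }
  return List::create(_["labels"] = labels, _["prob"] = joint);
}
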