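// Single-precision inference engine for the fragment generator.
//
// Training runs in double precision (model.cpp); search-time sampling is
// memory-bandwidth-bound on the GRU weight matrices, so the search uses a
// float copy of the parameters held behind an external pointer, with the
// per-step valence masking, the rollout loop and the candidate expansion
// fused into single calls. All randomness comes in as pre-drawn U(0,1)
// numbers from R's RNG, so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <array>
using namespace Rcpp;

namespace {

typedef arma::fmat fm;
typedef arma::frowvec fr;

fm to_f(const NumericMatrix& m) {
  fm out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}

struct CompiledModel {
  int L;
  bool edge_typed;
  int n_elements;
  int S, E, D;
  std::vector<std::vector<fm> > encW; // [layer][0..3]
  std::vector<fr> encb;
  fm atom_W1, atom_W2, emb, init_W;
  fr atom_b1, atom_b2, init_b;
  fm g1Wx, g1Wh, g2Wx, g2Wh, bond_W1, bond_W2;
  fr g1bx, g1bh, g2bx, g2bh, bond_b1, bond_b2;
  arma::ivec max_val; // per vocabulary element
};

fr frow(const List& p, const std::string& n) {
  NumericMatrix m = p[n];
  fr out(m.ncol());
  for (int j = 0; j < m.ncol(); ++j) out(j) = (float)m(0, j);
  return out;
}

inline fr softmax_f(const fr& x) {
  fr e = arma::exp(x - x.max());
  return e / arma::accu(e);
}

void x_encode(const CompiledModel& M, const arma::ivec& atoms,
              const arma::imat& bonds, fm& Hn, fr& hg) {
  int n = atoms.n_elem;
  fm X(n, M.n_elements, arma::fill::zeros);
  for (int i = 0; i < n; ++i) X(i, atoms(i) - 1) = 1.0f;
  arma::fvec deg(n, arma::fill::zeros);
  for (arma::uword r = 0; r < bonds.n_rows; ++r) {
    deg(bonds(r, 0) - 1) += 1.0f;
    deg(bonds(r, 1) - 1) += 1.0f;
  }
  int nA = M.edge_typed ? 3 : 1;
  std::vector<fm> A(nA, fm(n, n, arma::fill::zeros));
  for (arma::uword r = 0; r < bonds.n_rows; ++r) {
    int i = bonds(r, 0) - 1, j = bonds(r, 1) - 1, o = bonds(r, 2);
    float w = 1.0f / std::sqrt(deg(i) * deg(j));
    int slot = M.edge_typed ? (o - 1) : 0;
    A[slot](i, j) = w;
    A[slot](j, i) = w;
  }
  fm H = X;
  for (int l = 1; l <= M.L; ++l) {
    fm Z = H * M.encW[l][0];
    for (int b = 0; b < nA; ++b) Z += A[b] * (H * M.encW[l][b + 1]);
    Z.each_row() += M.encb[l];
    H = arma::clamp(Z, 0.0f, arma::datum::inf);
  }
  Hn = H;
  hg = arma::sum(Hn, 0);
}

fr atom_dist(const CompiledModel& M, const fr& hg) {
  fr u1 = arma::clamp(hg * M.atom_W1 + M.atom_b1, 0.0f, arma::datum::inf);
  return softmax_f(u1 * M.atom_W2 + M.atom_b2);
}

// batched GRU cell: row r of X is the input for row r of Hs; each weight
// matrix is streamed once per call (gemm), not once per candidate
void x_gru_batch(const fm& X, fm& Hs, const fm& Wx, const fm& Wh,
                 const fr& bx, const fr& bh, int S) {
  fm Gx = X * Wx;
  Gx.each_row() += bx;
  fm Gh = Hs * Wh;
  Gh.each_row() += bh;
  fm R = 1.0f / (1.0f + arma::exp(-(Gx.cols(0, S - 1) + Gh.cols(0, S - 1))));
  fm Z = 1.0f / (1.0f + arma::exp(-(Gx.cols(S, 2 * S - 1) + Gh.cols(S, 2 * S - 1))));
  fm N = arma::tanh(Gx.cols(2 * S, 3 * S - 1) + R % Gh.cols(2 * S, 3 * S - 1));
  Hs = (1.0f - Z) % N + Z % Hs;
}

// GRU initial states for a set of candidate atom labels
void init_states(const CompiledModel& M, const std::vector<int>& labs,
                 const fr& hg, fm& S1, fm& S2) {
  int m = labs.size();
  S1.set_size(m, M.S);
  S2.set_size(m, M.S);
  for (int r = 0; r < m; ++r) {
    fr c = arma::join_rows(fr(M.emb.row(labs[r] - 1)), hg);
    fr s0 = arma::tanh(c * M.init_W + M.init_b);
    for (int j = 0; j < M.S; ++j) {
      S1(r, j) = s0(j);
      S2(r, j) = s0(M.S + j);
    }
  }
}

// masked pick from a 4-way bond distribution (greedy or inverse-CDF)
int pick_bond(fr p, int free_t, int rem, bool greedy, double u,
              float* chosen_p) {
  for (int o = 1; o <= 3; ++o)
    if (o > free_t || o > rem) p(o - 1) = 0.0f;
  float tot = arma::accu(p);
  if (tot <= 0.0f) { *chosen_p = 1.0f; return 4; }
  p /= tot;
  int pick = 3;
  if (greedy) {
    pick = p.index_max();
  } else {
    float acc = 0.0f;
    for (int k = 0; k < 4; ++k) {
      acc += p(k);
      if (u <= acc) { pick = k; break; }
    }
  }
  *chosen_p = p(pick);
  return pick + 1;
}

arma::imat bonds_from_R(const IntegerMatrix& bm) {
  arma::imat bonds(bm.nrow(), 3);
  for (int r = 0; r < bm.nrow(); ++r)
    for (int c = 0; c < 3; ++c) bonds(r, c) = bm(r, c);
  return bonds;
}

} // namespace

// Build the float inference model. max_valence: per vocabulary element.
// [[Rcpp::export]]
SEXP mt_compile(List params, List cfg, IntegerVector max_valence) {
  CompiledModel* M = new CompiledModel();
  M->L = as<int>(cfg["mpnn_layers"]);
  M->edge_typed = as<std::string>(cfg["flavor"]) == "mpnn";
  M->n_elements = as<int>(cfg["n_elements"]);
  M->encW.resize(M->L + 1);
  M->encb.resize(M->L + 1);
  for (int l = 1; l <= M->L; ++l) {
    std::string sl = std::to_string(l);
    M->encW[l].resize(4);
    for (int b = 0; b <= 3; ++b)
      M->encW[l][b] = to_f(params["enc_W" + std::to_string(b) + "_" + sl]);
    M->encb[l] = frow(params, "enc_b_" + sl);
  }
  M->atom_W1 = to_f(params["atom_W1"]); M->atom_b1 = frow(params, "atom_b1");
  M->atom_W2 = to_f(params["atom_W2"]); M->atom_b2 = frow(params, "atom_b2");
  M->emb = to_f(params["emb"]);
  M->init_W = to_f(params["init_W"]); M->init_b = frow(params, "init_b");
  M->g1Wx = to_f(params["gru1_Wx"]); M->g1Wh = to_f(params["gru1_Wh"]);
  M->g1bx = frow(params, "gru1_bx"); M->g1bh = frow(params, "gru1_bh");
  M->g2Wx = to_f(params["gru2_Wx"]); M->g2Wh = to_f(params["gru2_Wh"]);
  M->g2bx = frow(params, "gru2_bx"); M->g2bh = frow(params, "gru2_bh");
  M->bond_W1 = to_f(params["bond_W1"]); M->bond_b1 = frow(params, "bond_b1");
  M->bond_W2 = to_f(params["bond_W2"]); M->bond_b2 = frow(params, "bond_b2");
  M->S = M->g1Wh.n_rows;
  M->E = M->emb.n_cols;
  M->D = M->atom_W1.n_rows;
  M->max_val = as<arma::ivec>(max_valence);
  XPtr<CompiledModel> xp(M, true);
  return xp;
}

// Atom-label distribution for a partial fragment (float path).
// [[Rcpp::export]]
NumericVector mt_x_atom_probs(SEXP xp_, IntegerVector atoms,
                              IntegerMatrix bonds) {
  XPtr<CompiledModel> xp(xp_);
  const CompiledModel& M = *xp;
  fr hg(M.D, arma::fill::zeros);
  fm Hn;
  if (atoms.size() > 0)
    x_encode(M, as<arma::ivec>(atoms), bonds_from_R(bonds), Hn, hg);
  fr pa = atom_dist(M, hg);
  NumericVector out(pa.n_elem);
  for (arma::uword i = 0; i < pa.n_elem; ++i) out[i] = pa(i);
  return out;
}

// One masked generation step. free_val must already include any valence
// reservation. unifs: first element drives the atom draw, then one per
// existing atom for the bonds. forced_atom > 0 skips the atom draw.
// stop = TRUE when the stop label is drawn or no bond survives.
// [[Rcpp::export]]
List mt_x_sample_step(SEXP xp_, IntegerVector atoms, IntegerMatrix bonds,
                      IntegerVector free_val, NumericVector unifs,
                      bool greedy = false, int forced_atom = 0) {
  XPtr<CompiledModel> xp(xp_);
  const CompiledModel& M = *xp;
  int n = atoms.size();
  fr hg(M.D, arma::fill::zeros);
  fm Hn;
  if (n > 0) x_encode(M, as<arma::ivec>(atoms), bonds_from_R(bonds), Hn, hg);
  fr pa = atom_dist(M, hg);
  int lab = forced_atom;
  double p_atom = 1.0;
  if (lab == 0) {
    if (greedy) {
      lab = pa.index_max() + 1;
    } else {
      float acc = 0.0f;
      lab = pa.n_elem;
      for (arma::uword k = 0; k < pa.n_elem; ++k) {
        acc += pa(k);
        if (unifs[0] <= acc) { lab = k + 1; break; }
      }
    }
    p_atom = pa(lab - 1);
  }
  if (lab == M.n_elements + 1)
    return List::create(_["stop"] = true, _["prob"] = p_atom);
  if (n == 0)
    return List::create(_["stop"] = false, _["atom_label"] = lab,
                        _["bond_labels"] = IntegerVector(0),
                        _["prob"] = p_atom);
  std::vector<int> labs(1, lab);
  fm S1, S2;
  init_states(M, labs, hg, S1, S2);
  int rem = M.max_val(lab - 1);
  IntegerVector labels(n);
  double joint = p_atom;
  bool any_bond = false;
  for (int t = 0; t < n; ++t) {
    fm x = Hn.row(t);
    x_gru_batch(x, S1, M.g1Wx, M.g1Wh, M.g1bx, M.g1bh, M.S);
    x_gru_batch(S1, S2, M.g2Wx, M.g2Wh, M.g2bx, M.g2bh, M.S);
    fr o1 = arma::clamp(fr(S2.row(0)) * M.bond_W1 + M.bond_b1, 0.0f,
                        arma::datum::inf);
    fr pb = softmax_f(o1 * M.bond_W2 + M.bond_b2);
    float cp;
    int bl = pick_bond(pb, free_val[t], rem, greedy, unifs[t + 1], &cp);
    labels[t] = bl;
    joint *= cp;
    if (bl < 4) { rem -= bl; any_bond = true; }
  }
  if (!any_bond) return List::create(_["stop"] = true, _["prob"] = joint);
  return List::create(_["stop"] = false, _["atom_label"] = lab,
                      _["bond_labels"] = labels, _["prob"] = joint);
}

// Complete a partial fragment by temperature-1 sampling under valence
// masks until the model stops, the state saturates, or max_atoms is hit.
// reserve_first keeps one valence unit of atom 1 for the later
// attachment bond. Returns the grown atom/bond lists.
// [[Rcpp::export]]
List mt_x_rollout(SEXP xp_, IntegerVector atoms0, IntegerMatrix bonds0,
                  int max_atoms, NumericVector unifs,
                  bool reserve_first = true, bool greedy = false) {
  XPtr<CompiledModel> xp(xp_);
  const CompiledModel& M = *xp;
  std::vector<int> atoms(atoms0.begin(), atoms0.end());
  std::vector<std::array<int, 3> > bonds;
  for (int r = 0; r < bonds0.nrow(); ++r)
    bonds.push_back(std::array<int, 3>{{bonds0(r, 0), bonds0(r, 1),
                                        bonds0(r, 2)}});
  std::vector<int> fv;
  for (size_t i = 0; i < atoms.size(); ++i)
    fv.push_back(M.max_val(atoms[i] - 1));
  for (size_t r = 0; r < bonds.size(); ++r) {
    fv[bonds[r][0] - 1] -= bonds[r][2];
    fv[bonds[r][1] - 1] -= bonds[r][2];
  }
  int used = 0;
  while ((int)atoms.size() < max_atoms) {
    int n = atoms.size();
    IntegerVector av(atoms.begin(), atoms.end());
    IntegerMatrix bm(bonds.size(), 3);
    for (size_t r = 0; r < bonds.size(); ++r)
      for (int c = 0; c < 3; ++c) bm(r, c) = bonds[r][c];
    IntegerVector free_adj(n);
    bool any_free = (n == 0);
    for (int i = 0; i < n; ++i) {
      int f = fv[i];
      if (reserve_first && i == 0) f = std::max(f - 1, 0);
      free_adj[i] = f;
      if (f > 0) any_free = true;
    }
    if (!any_free) break; // saturated state
    if (used + n + 1 > unifs.size())
      stop("rollout ran out of pre-drawn random numbers");
    NumericVector u(n + 1);
    for (int i = 0; i <= n; ++i) u[i] = unifs[used + i];
    used += n + 1;
    List st = mt_x_sample_step(xp_, av, bm, free_adj, u, greedy, 0);
    if (as<bool>(st["stop"])) break;
    int lab = as<int>(st["atom_label"]);
    IntegerVector bl = st["bond_labels"];
    atoms.push_back(lab);
    fv.push_back(M.max_val(lab - 1));
    for (int t = 0; t < bl.size(); ++t) {
      if (bl[t] != 4) {
        bonds.push_back(std::array<int, 3>{{t + 1, (int)atoms.size(), bl[t]}});
        fv[t] -= bl[t];
        fv.back() -= bl[t];
      }
    }
  }
  IntegerMatrix bm(bonds.size(), 3);
  for (size_t r = 0; r < bonds.size(); ++r)
    for (int c = 0; c < 3; ++c) bm(r, c) = bonds[r][c];
  return List::create(_["atoms"] = IntegerVector(atoms.begin(), atoms.end()),
                      _["bonds"] = bm, _["n_unifs_used"] = used);
}

// Expansion proposals: the k most probable atom labels, each completed
// with a greedy masked bond assignment. The candidates share one encoder
// pass, and the greedy decodes run as one batch so each GRU weight matrix
// is streamed once per sequence position. Candidates whose bonds all come
// out "none" are dropped (they are terminal proposals, like the stop
// label). Returns labels, a bond-label matrix (candidates x state atoms),
// joint probabilities, and whether the stop label made the top k.
// [[Rcpp::export]]
List mt_x_expand(SEXP xp_, IntegerVector atoms, IntegerMatrix bonds,
                 IntegerVector free_val, int k) {
  XPtr<CompiledModel> xp(xp_);
  const CompiledModel& M = *xp;
  int n = atoms.size();
  fr hg(M.D, arma::fill::zeros);
  fm Hn;
  if (n > 0) x_encode(M, as<arma::ivec>(atoms), bonds_from_R(bonds), Hn, hg);
  fr pa = atom_dist(M, hg);
  arma::uvec ord = arma::sort_index(arma::conv_to<arma::fvec>::from(pa.t()),
                                    "descend");
  int kk = std::min<int>(k, pa.n_elem);
  std::vector<int> labs;
  bool has_stop = false;
  double stop_p = 0.0;
  for (int i = 0; i < kk; ++i) {
    int lab = ord(i) + 1;
    if (lab == M.n_elements + 1) {
      has_stop = true;
      stop_p = pa(ord(i));
    } else {
      labs.push_back(lab);
    }
  }
  int m = labs.size();
  IntegerVector out_labs(m);
  NumericVector out_probs(m);
  LogicalVector keep(m);
  IntegerMatrix bond_mat(m, n);
  for (int r = 0; r < m; ++r) {
    out_labs[r] = labs[r];
    out_probs[r] = pa(labs[r] - 1);
    keep[r] = (n == 0); // with no state atoms a bare first atom is valid
  }
  if (m > 0 && n > 0) {
    fm S1, S2;
    init_states(M, labs, hg, S1, S2);
    std::vector<int> rem(m);
    for (int r = 0; r < m; ++r) rem[r] = M.max_val(labs[r] - 1);
    fm Xrep(m, M.D);
    for (int t = 0; t < n; ++t) {
      for (int r = 0; r < m; ++r) Xrep.row(r) = Hn.row(t);
      x_gru_batch(Xrep, S1, M.g1Wx, M.g1Wh, M.g1bx, M.g1bh, M.S);
      x_gru_batch(S1, S2, M.g2Wx, M.g2Wh, M.g2bx, M.g2bh, M.S);
      fm O1 = S2 * M.bond_W1;
      O1.each_row() += M.bond_b1;
      O1 = arma::clamp(O1, 0.0f, arma::datum::inf);
      fm Logits = O1 * M.bond_W2;
      Logits.each_row() += M.bond_b2;
      for (int r = 0; r < m; ++r) {
        fr pb = softmax_f(fr(Logits.row(r)));
        float cp;
        int bl = pick_bond(pb, free_val[t], rem[r], true, 0.0, &cp);
        bond_mat(r, t) = bl;
        out_probs[r] *= cp;
        if (bl < 4) { rem[r] -= bl; keep[r] = true; }
      }
    }
  }
  return List::create(_["atom_labels"] = out_labs, _["bond_labels"] = bond_mat,
                      _["probs"] = out_probs, _["keep"] = keep,
                      _["has_stop"] = has_stop, _["stop_prob"] = stop_p);
}
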