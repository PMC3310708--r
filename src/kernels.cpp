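// Numerical kernels: rigid-body (Kabsch) superposition, quasi-rigid
// partition objective and annealing moves, fixed-axis rotation fits.
// Coordinates come in as N x 3 matrices (reference) and N x 3 x F cubes
// (trajectories), Angstrom. Domain labels are 1..q.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Optimal rigid superposition of reference points P onto target points Q
// (both n x 3). Returns the residual sum of squares; optionally the
// rotation R and translation t with q_pred = R p + t (column vectors).
static double kabsch_sse(const arma::mat& P, const arma::mat& Q,
                         arma::mat* Rout = nullptr,
                         arma::vec* tout = nullptr) {
  arma::rowvec pc = arma::mean(P, 0), qc = arma::mean(Q, 0);
  arma::mat Pc = P;  Pc.each_row() -= pc;
  arma::mat Qc = Q;  Qc.each_row() -= qc;
  arma::mat H = Pc.t() * Qc;  // 3x3 cross-covariance
  arma::mat U, V;  arma::vec s;
  if (!arma::svd(U, s, V, H))
    stop("SVD failed in rigid-body superposition");
  double d = (arma::det(V * U.t()) < 0.0) ? -1.0 : 1.0;
  double sse = arma::accu(Pc % Pc) + arma::accu(Qc % Qc)
             - 2.0 * (s(0) + s(1) + d * s(2));
  if (sse < 0.0) sse = 0.0;  // round-off guard
  if (Rout != nullptr) {
    arma::mat D = arma::eye(3, 3);  D(2, 2) = d;
    *Rout = V * D * U.t();
    if (tout != nullptr) *tout = qc.t() - (*Rout) * pc.t();
  }
  return sse;
}

// [[Rcpp::export(name = ".cpp_kabsch")]]
List cpp_kabsch(const arma::mat& P, const arma::mat& Q) {
  arma::mat R;  arma::vec t;
  double sse = kabsch_sse(P, Q, &R, &t);
  return List::create(_["rotation"] = R, _["translation"] = t,
                      _["sse"] = sse);
}

// Residual sum of squares of a partition: per frame and domain, the best
// rigid placement of the reference domain onto the frame's domain.
static double partition_sse(const arma::mat& ref, const arma::cube& frames,
                            const std::vector<arma::uvec>& members) {
  const arma::uword F = frames.n_slices;
  double total = 0.0;
  for (arma::uword l = 0; l < members.size(); ++l) {
    const arma::mat refd = ref.rows(members[l]);
    for (arma::uword f = 0; f < F; ++f) {
      arma::mat tgt = frames.slice(f);
      total += kabsch_sse(refd, tgt.rows(members[l]));
    }
  }
  return total;
}

static std::vector<arma::uvec> member_lists(const arma::ivec& assign, int q) {
  std::vector<std::vector<arma::uword>> acc(q);
  for (arma::uword i = 0; i < assign.n_elem; ++i)
    acc[assign(i) - 1].push_back(i);
  std::vector<arma::uvec> out(q);
  for (int l = 0; l < q; ++l) out[l] = arma::uvec(acc[l]);
  return out;
}

// [[Rcpp::export(name = ".cpp_partition_sse")]]
double cpp_partition_sse(const arma::mat& ref, const arma::cube& frames,
                         const arma::ivec& assignment, int q) {
  return partition_sse(ref, frames, member_lists(assignment, q));
}

// Full fit: rotations (3x3xq*F, domain fastest), translations, per-domain
// per-frame SSE and per-frame total SSE.
// [[Rcpp::export(name = ".cpp_rigid_fit")]]
List cpp_rigid_fit(const arma::mat& ref, const arma::cube& frames,
                   const arma::ivec& assignment, int q) {
  const arma::uword F = frames.n_slices;
  std::vector<arma::uvec> members = member_lists(assignment, q);
  arma::cube rot(3, 3, (arma::uword)q * F);
  arma::mat trans(3, (arma::uword)q * F);
  arma::mat dsse(q, F, arma::fill::zeros);
  arma::vec fsse(F, arma::fill::zeros);
  for (int l = 0; l < q; ++l) {
    const arma::mat refd = ref.rows(members[l]);
    for (arma::uword f = 0; f < F; ++f) {
      arma::mat tgt = frames.slice(f);
      arma::mat R;  arma::vec t;
      double sse = kabsch_sse(refd, tgt.rows(members[l]), &R, &t);
      rot.slice(l + (arma::uword)q * f) = R;
      trans.col(l + (arma::uword)q * f) = t;
      dsse(l, f) = sse;
      fsse(f) += sse;
    }
  }
  return List::create(_["rotations"] = rot, _["translations"] = trans,
                      _["domain_frame_sse"] = dsse,
                      _["frame_sse"] = fsse);
}

static arma::vec domain_sse_vec(const arma::mat& ref, const arma::cube& frames,
                                const std::vector<arma::uvec>& members) {
  arma::vec out(members.size(), arma::fill::zeros);
  for (arma::uword l = 0; l < members.size(); ++l) {
    const arma::mat refd = ref.rows(members[l]);
    for (arma::uword f = 0; f < frames.n_slices; ++f) {
      arma::mat tgt = frames.slice(f);
      out(l) += kabsch_sse(refd, tgt.rows(members[l]));
    }
  }
  return out;
}

static double one_domain_sse(const arma::mat& ref, const arma::cube& frames,
                             const std::vector<arma::uword>& idx) {
  if (idx.empty()) return 0.0;
  arma::uvec u(idx);
  const arma::mat refd = ref.rows(u);
  double s = 0.0;
  for (arma::uword f = 0; f < frames.n_slices; ++f) {
    arma::mat tgt = frames.slice(f);
    s += kabsch_sse(refd, tgt.rows(u));
  }
  return s;
}

// Simulated annealing over single-residue relabelling moves, boundary
// residues preferred. `nbr` holds 1-based neighbour indices from the
// reference contact map. Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export(name = ".cpp_anneal")]]
List cpp_anneal(const arma::mat& ref, const arma::cube& frames,
                const arma::ivec& assignment0, int q, const List& nbr,
                int n_moves, int min_size, double t0_frac, double t_end_frac) {
  const arma::uword N = ref.n_rows, F = frames.n_slices;
  const double norm = 3.0 * (double)N * (double)F;
  arma::ivec assign = assignment0;
  std::vector<std::vector<int>> neigh(N);
  for (arma::uword i = 0; i < N; ++i) {
    IntegerVector v = nbr[i];
    for (int j = 0; j < v.size(); ++j) neigh[i].push_back(v[j] - 1);
  }
  std::vector<int> size(q, 0);
  for (arma::uword i = 0; i < N; ++i) size[assign(i) - 1]++;
  std::vector<arma::uvec> members = member_lists(assign, q);
  arma::vec dsse = domain_sse_vec(ref, frames, members);
  double total = arma::accu(dsse);
  arma::ivec best = assign;
  double best_sse = total;
  double scale = total / norm;
  if (scale <= 0.0) scale = 1e-12;
  double T0 = t0_frac * scale, Tend = t_end_frac * scale;
  if (Tend <= 0.0) Tend = 1e-15;
  double alpha = (n_moves > 1) ? std::pow(Tend / T0, 1.0 / (n_moves - 1)) : 1.0;
  double T = T0;

  // mutable member vectors as std::vector for cheap add/remove
  std::vector<std::vector<arma::uword>> mem(q);
  for (int l = 0; l < q; ++l)
    mem[l] = arma::conv_to<std::vector<arma::uword>>::from(members[l]);

  for (int m = 0; m < n_moves; ++m, T *= alpha) {
    // propose: boundary residue, relabel to a differing neighbour's domain
    int i = -1, to = -1;
    for (int tries = 0; tries < 12; ++tries) {
      int cand = (int)(unif_rand() * N);
      if (cand >= (int)N) cand = N - 1;
      int cur = assign(cand);
      std::vector<int> alt;
      for (int j : neigh[cand])
        if (assign(j) != cur) alt.push_back(assign(j));
      if (!alt.empty()) {
        i = cand;
        to = alt[(int)(unif_rand() * alt.size()) % alt.size()];
        break;
      }
    }
    if (i < 0) {  // fallback: uniform residue, uniform other label
      i = (int)(unif_rand() * N);  if (i >= (int)N) i = N - 1;
      to = 1 + (int)(unif_rand() * q);  if (to > q) to = q;
      if (to == assign(i)) continue;
    }
    int from = assign(i);
    if (to == from || size[from - 1] <= min_size) continue;

    std::vector<arma::uword> mf = mem[from - 1], mt = mem[to - 1];
    mf.erase(std::find(mf.begin(), mf.end(), (arma::uword)i));
    mt.push_back((arma::uword)i);
    double sf = one_domain_sse(ref, frames, mf);
    double st = one_domain_sse(ref, frames, mt);
    double delta = (sf + st) - (dsse(from - 1) + dsse(to - 1));
    bool accept = delta < 0.0 ||
                  unif_rand() < std::exp(-(delta / norm) / T);
    if (accept) {
      assign(i) = to;
      size[from - 1]--;  size[to - 1]++;
      mem[from - 1] = mf;  mem[to - 1] = mt;
      dsse(from - 1) = sf;  dsse(to - 1) = st;
      total += delta;
      if (total < best_sse) { best_sse = total; best = assign; }
    }
  }
  return List::create(_["assignment"] = best, _["sse"] = best_sse,
                      _["final_assignment"] = assign, _["final_sse"] = total);
}

// Greedy polish: best-improvement single-residue moves among neighbouring
// domains until no move improves the residual.
// [[Rcpp::export(name = ".cpp_polish")]]
List cpp_polish(const arma::mat& ref, const arma::cube& frames,
                const arma::ivec& assignment0, int q, const List& nbr,
                int min_size, int max_passes) {
  const arma::uword N = ref.n_rows;
  arma::ivec assign = assignment0;
  std::vector<std::vector<int>> neigh(N);
  for (arma::uword i = 0; i < N; ++i) {
    IntegerVector v = nbr[i];
    for (int j = 0; j < v.size(); ++j) neigh[i].push_back(v[j] - 1);
  }
  std::vector<int> size(q, 0);
  for (arma::uword i = 0; i < N; ++i) size[assign(i) - 1]++;
  std::vector<arma::uvec> members = member_lists(assign, q);
  arma::vec dsse = domain_sse_vec(ref, frames, members);
  double total = arma::accu(dsse);
  std::vector<std::vector<arma::uword>> mem(q);
  for (int l = 0; l < q; ++l)
    mem[l] = arma::conv_to<std::vector<arma::uword>>::from(members[l]);
  const double eps = 1e-12;

  for (int pass = 0; pass < max_passes; ++pass) {
    bool moved = false;
    for (arma::uword i = 0; i < N; ++i) {
      int from = assign(i);
      if (size[from - 1] <= min_size) continue;
      std::vector<int> cand;
      for (int j : neigh[i]) {
        int lab = assign(j);
        if (lab != from &&
            std::find(cand.begin(), cand.end(), lab) == cand.end())
          cand.push_back(lab);
      }
      if (cand.empty()) continue;
      std::vector<arma::uword> mf = mem[from - 1];
      mf.erase(std::find(mf.begin(), mf.end(), i));
      double sf = one_domain_sse(ref, frames, mf);
      int best_to = -1;
      double best_delta = -eps, best_st = 0.0;
      for (int to : cand) {
        std::vector<arma::uword> mt = mem[to - 1];
        mt.push_back(i);
        double st = one_domain_sse(ref, frames, mt);
        double delta = (sf + st) - (dsse(from - 1) + dsse(to - 1));
        if (delta < best_delta) {
          best_delta = delta;  best_to = to;  best_st = st;
        }
      }
      if (best_to > 0) {
        std::vector<arma::uword> mt = mem[best_to - 1];
        mt.push_back(i);
        assign(i) = best_to;
        size[from - 1]--;  size[best_to - 1]++;
        mem[from - 1] = mf;  mem[best_to - 1] = mt;
        dsse(from - 1) = sf;  dsse(best_to - 1) = best_st;
        total += best_delta;
        moved = true;
      }
    }
    if (!moved) break;
  }
  return List::create(_["assignment"] = assign, _["sse"] = total);
}

// K-means-style alternation: fit per-domain per-frame rigid transforms,
// then reassign every residue to the domain whose transforms predict its
// trajectory best; repeat until the assignment is stable. Each half-step
// cannot increase the total residual, so this descends monotonically and
// can move coherent blocks that single-residue moves cannot.
// [[Rcpp::export(name = ".cpp_reassign")]]
List cpp_reassign(const arma::mat& ref, const arma::cube& frames,
                  const arma::ivec& assignment0, int q, int min_size,
                  int max_iter) {
  const arma::uword N = ref.n_rows, F = frames.n_slices;
  arma::ivec assign = assignment0;
  for (int it = 0; it < max_iter; ++it) {
    std::vector<arma::uvec> members = member_lists(assign, q);
    for (int l = 0; l < q; ++l)
      if (members[l].n_elem < 3) return List::create(
        _["assignment"] = assign,
        _["sse"] = partition_sse(ref, frames, members));
    // per-residue, per-domain prediction error under the fitted
    // transforms
    arma::mat err(N, q, arma::fill::zeros);
    for (int l = 0; l < q; ++l) {
      const arma::mat refd = ref.rows(members[l]);
      for (arma::uword f = 0; f < F; ++f) {
        arma::mat tgt = frames.slice(f);
        arma::mat R;  arma::vec t;
        kabsch_sse(refd, tgt.rows(members[l]), &R, &t);
        arma::mat pred = ref * R.t();
        pred.each_row() += t.t();
        arma::mat d = pred - tgt;
        err.col(l) += arma::sum(d % d, 1);
      }
    }
    arma::ivec next(N);
    for (arma::uword i = 0; i < N; ++i)
      next(i) = (int)err.row(i).index_min() + 1;
    // repair undersized domains: pull in the residues with the least
    // extra cost, never shrinking another domain below min_size
    std::vector<int> size(q, 0);
    for (arma::uword i = 0; i < N; ++i) size[next(i) - 1]++;
    for (int l = 0; l < q; ++l) {
      while (size[l] < min_size) {
        double bestGap = std::numeric_limits<double>::infinity();
        int bestI = -1;
        for (arma::uword i = 0; i < N; ++i) {
          int cur = next(i);
          if (cur == l + 1 || size[cur - 1] <= min_size) continue;
          double gap = err(i, l) - err(i, cur - 1);
          if (gap < bestGap) { bestGap = gap; bestI = (int)i; }
        }
        if (bestI < 0) break;
        size[next(bestI) - 1]--;
        next(bestI) = l + 1;
        size[l]++;
      }
    }
    if (arma::all(next == assign)) break;
    assign = next;
  }
  std::vector<arma::uvec> members = member_lists(assign, q);
  return List::create(_["assignment"] = assign,
                      _["sse"] = partition_sse(ref, frames, members));
}

// Superpose every frame onto `ref` by least squares over `fit_idx`
// (1-based); the fitted transform is applied to all atoms of the frame.
// [[Rcpp::export(name = ".cpp_superpose_frames")]]
arma::cube cpp_superpose_frames(const arma::cube& frames, const arma::mat& ref,
                                const arma::uvec& fit_idx) {
  arma::uvec idx = fit_idx - 1;
  arma::cube out(frames.n_rows, 3, frames.n_slices);
  for (arma::uword f = 0; f < frames.n_slices; ++f) {
    arma::mat X = frames.slice(f);
    arma::mat R;  arma::vec t;
    // map frame coordinates into the reference frame: fit frame -> ref
    kabsch_sse(X.rows(idx), ref.rows(idx), &R, &t);
    arma::mat Xt = X * R.t();
    Xt.each_row() += t.t();
    out.slice(f) = Xt;
  }
  return out;
}

// Fixed-axis rotation fit. For points p (reference, core-fixed frame),
// axis through `anchor` with unit direction `u`, the frame residual
//   SSE(theta) = S_perp + S_c - 2 (A cos theta + B sin theta)
// is minimised at theta = atan2(B, A), giving S_perp + S_c - 2 sqrt(A^2+B^2).
static void axis_decompose(const arma::mat& P, const arma::vec& a,
                           const arma::vec& u, arma::mat& base,
                           arma::mat& vperp, arma::mat& w, double& sperp) {
  const arma::uword n = P.n_rows;
  base.set_size(n, 3);  vperp.set_size(n, 3);  w.set_size(n, 3);
  sperp = 0.0;
  for (arma::uword k = 0; k < n; ++k) {
    arma::vec v = P.row(k).t() - a;
    arma::vec vpar = arma::dot(v, u) * u;
    arma::vec vp = v - vpar;
    arma::vec wk = arma::cross(u, vp);
    base.row(k) = (a + vpar).t();
    vperp.row(k) = vp.t();
    w.row(k) = wk.t();
    sperp += arma::dot(vp, vp);
  }
}

// [[Rcpp::export(name = ".cpp_axis_eval")]]
List cpp_axis_eval(const arma::mat& refmov, const arma::cube& movframes,
                   const arma::vec& anchor, const arma::vec& orient) {
  arma::mat base, vperp, w;
  double sperp;
  axis_decompose(refmov, anchor, orient, base, vperp, w, sperp);
  const arma::uword F = movframes.n_slices;
  arma::vec angles(F), fsse(F);
  double total = 0.0;
  for (arma::uword f = 0; f < F; ++f) {
    arma::mat C = movframes.slice(f) - base;
    double A = arma::accu(vperp % C), B = arma::accu(w % C);
    double Sc = arma::accu(C % C);
    double amp = std::sqrt(A * A + B * B);
    angles(f) = (amp > 0.0) ? std::atan2(B, A) : 0.0;
    double sse = sperp + Sc - 2.0 * amp;
    if (sse < 0.0) sse = 0.0;
    fsse(f) = sse;
    total += sse;
  }
  return List::create(_["sse"] = total, _["angles_rad"] = angles,
                      _["frame_sse"] = fsse);
}

// Exhaustive scan over candidate anchors x orientations; returns 1-based
// indices of the best pair and the SSE of every pair.
// [[Rcpp::export(name = ".cpp_axis_scan")]]
List cpp_axis_scan(const arma::mat& refmov, const arma::cube& movframes,
                   const arma::mat& anchors, const arma::mat& orients) {
  const arma::uword A = anchors.n_rows, O = orients.n_rows,
                    F = movframes.n_slices;
  double best = std::numeric_limits<double>::infinity();
  arma::uword best_a = 0, best_o = 0;
  arma::mat sse_mat(A, O);
  arma::mat base, vperp, w;
  for (arma::uword ai = 0; ai < A; ++ai) {
    arma::vec a = anchors.row(ai).t();
    for (arma::uword oi = 0; oi < O; ++oi) {
      arma::vec u = orients.row(oi).t();
      double sperp;
      axis_decompose(refmov, a, u, base, vperp, w, sperp);
      double total = 0.0;
      for (arma::uword f = 0; f < F; ++f) {
        arma::mat C = movframes.slice(f) - base;
        double Ac = arma::accu(vperp % C), Bc = arma::accu(w % C);
        total += sperp + arma::accu(C % C)
               - 2.0 * std::sqrt(Ac * Ac + Bc * Bc);
      }
      sse_mat(ai, oi) = total;
      if (total < best) { best = total; best_a = ai; best_o = oi; }
    }
  }
  return List::create(_["anchor_index"] = (int)(best_a + 1),
                      _["orientation_index"] = (int)(best_o + 1),
                      _["sse"] = best, _["sse_matrix"] = sse_mat);
}
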