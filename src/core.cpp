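#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Least-squares superposition of A onto B (both n x 3), reflection-corrected.
// Returns false when the covariance is too degenerate to define a rotation.
static bool kabsch_fit(const arma::mat& A, const arma::mat& B,
                       arma::mat& Rrot, arma::vec& tvec, double& rmsd,
                       bool strict = false) {
  const arma::rowvec ca = arma::mean(A, 0);
  const arma::rowvec cb = arma::mean(B, 0);
  arma::mat Ac = A.each_row() - ca;
  arma::mat Bc = B.each_row() - cb;
  arma::mat H = Ac.t() * Bc;              // 3 x 3
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) return false;
  if (strict && s(1) <= 1e-8 * std::max(1.0, s(0))) return false; // collinear
  arma::mat D = arma::eye(3, 3);
  if (arma::det(V * U.t()) < 0.0) D(2, 2) = -1.0;
  Rrot = V * D * U.t();
  tvec = cb.t() - Rrot * ca.t();
  arma::mat Afit = (Rrot * A.t()).t();
  Afit.each_row() += tvec.t();
  rmsd = std::sqrt(arma::accu(arma::square(Afit - B)) / A.n_rows);
  return true;
}

// [[Rcpp::export]]
List cpp_kabsch(const arma::mat& A, const arma::mat& B, bool strict) {
  arma::mat Rrot;
  arma::vec tvec;
  double rmsd;
  if (!kabsch_fit(A, B, Rrot, tvec, rmsd, strict))
    stop("degenerate (collinear or rank-deficient) coordinates: superposition undefined");
  return List::create(_["rotation"] = Rrot, _["translation"] = tvec,
                      _["rmsd"] = rmsd);
}

struct Best {
  arma::ivec gdt_counts;   // per cutoff
  double tm_sum;
  arma::mat tm_rot;
  arma::vec tm_tr;
  Best(int ncut) : gdt_counts(ncut, arma::fill::zeros), tm_sum(-1.0),
                   tm_rot(arma::eye(3, 3)), tm_tr(3, arma::fill::zeros) {}
};

// Evaluate one superposition against every GDT cutoff and the TM sum.
static void evaluate(const arma::mat& M, const arma::mat& Rf,
                     const arma::mat& Rrot, const arma::vec& tvec,
                     const arma::vec& cutoffs, double d0, Best& best,
                     arma::vec& dist_out) {
  arma::mat Mfit = (Rrot * M.t()).t();
  Mfit.each_row() += tvec.t();
  arma::vec d = arma::sqrt(arma::sum(arma::square(Mfit - Rf), 1));
  dist_out = d;
  for (arma::uword k = 0; k < cutoffs.n_elem; ++k) {
    int cnt = arma::accu(d <= cutoffs(k));
    if (cnt > best.gdt_counts(k)) best.gdt_counts(k) = cnt;
  }
  double tm = arma::accu(1.0 / (1.0 + arma::square(d / d0)));
  if (tm > best.tm_sum) {
    best.tm_sum = tm;
    best.tm_rot = Rrot;
    best.tm_tr = tvec;
  }
}

static void refine_track(const arma::mat& M, const arma::mat& Rf,
                         arma::uvec sel, double keep_cut,
                         const arma::vec& cutoffs, double d0, Best& best,
                         int max_rounds) {
  arma::mat Rrot;
  arma::vec tvec;
  double rmsd;
  arma::vec d;
  for (int round = 0; round < max_rounds; ++round) {
    if (sel.n_elem < 3) return;
    if (!kabsch_fit(M.rows(sel), Rf.rows(sel), Rrot, tvec, rmsd)) return;
    evaluate(M, Rf, Rrot, tvec, cutoffs, d0, best, d);
    arma::uvec nsel = arma::find(d <= keep_cut);
    if (nsel.n_elem < 3) {                 // keep the 3 closest residues
      arma::uvec ord = arma::sort_index(d);
      nsel = ord.head(3);
    }
    if (nsel.n_elem == sel.n_elem && arma::all(nsel == sel)) return;
    sel = nsel;
  }
}

// Superposition search shared by GDT-TS and TM-score: seeds from contiguous
// fragments (lengths 4/8/16/N, stride 4), each iteratively extended per
// cutoff; optional exhaustive subset enumeration for small chains.
// [[Rcpp::export]]
List cpp_score_pair(const arma::mat& M, const arma::mat& Rf, double Lref,
                    const arma::vec& cutoffs, double d0, bool exact,
                    int max_rounds) {
  const int n = M.n_rows;
  Best best((int)cutoffs.n_elem);
  arma::mat Rrot;
  arma::vec tvec;
  double rmsd_all = NA_REAL, rmsd;
  arma::vec d;

  if (kabsch_fit(M, Rf, Rrot, tvec, rmsd_all))
    evaluate(M, Rf, Rrot, tvec, cutoffs, d0, best, d);

  if (exact && n <= 20) {
    const unsigned long nmask = 1UL << n;
    for (unsigned long mask = 0; mask < nmask; ++mask) {
      int pc = __builtin_popcountl(mask);
      if (pc < 3) continue;
      arma::uvec sel(pc);
      int k = 0;
      for (int i = 0; i < n; ++i)
        if (mask & (1UL << i)) sel(k++) = i;
      if (!kabsch_fit(M.rows(sel), Rf.rows(sel), Rrot, tvec, rmsd)) continue;
      evaluate(M, Rf, Rrot, tvec, cutoffs, d0, best, d);
    }
  } else {
    const int lens[4] = {4, 8, 16, n};
    for (int li = 0; li < 4; ++li) {
      int len = lens[li];
      if (len < 3 || len > n) continue;
      if (li < 3 && len == n) continue;    // avoid duplicating the full fit
      for (int s = 0; s + len <= n; s += 4) {
        arma::uvec frag = arma::regspace<arma::uvec>(s, s + len - 1);
        for (arma::uword k = 0; k < cutoffs.n_elem; ++k)
          refine_track(M, Rf, frag, cutoffs(k), cutoffs, d0, best, max_rounds);
        refine_track(M, Rf, frag, std::max(d0, 1.0) + 1.0, cutoffs, d0, best,
                     max_rounds);
      }
    }
  }

  arma::vec fr = arma::conv_to<arma::vec>::from(best.gdt_counts) / (double)n;
  return List::create(
      _["gdt_fractions"] = fr, _["gdt_ts"] = arma::mean(fr),
      _["tm_score"] = best.tm_sum / Lref, _["rmsd"] = rmsd_all,
      _["tm_rotation"] = best.tm_rot, _["tm_translation"] = best.tm_tr);
}
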