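#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Accumulations use long double so results agree bitwise with base R's
// sum()/rowSums()/colSums(), which accumulate in extended precision. The
// pure-R engine in train_model(engine = "r") relies on this to produce
// bit-identical traces.

static inline double sqdist(const double* x, const double* w, int dim) {
  long double acc = 0.0L;
  for (int k = 0; k < dim; ++k) {
    double d = x[k] - w[k];
    acc += d * d;
  }
  return (double) acc;
}

// argmin of input-weight squared distance; ties -> lowest index
static int bmu_of(const std::vector<double>& W, int n, int dim,
                  const double* x, double* d2out) {
  int best = 0;
  double bestd = sqdist(x, &W[0], dim);
  for (int i = 1; i < n; ++i) {
    double d = sqdist(x, &W[(size_t) i * dim], dim);
    if (d < bestd) { bestd = d; best = i; }
  }
  if (d2out) *d2out = bestd;
  return best;
}

// Gaussian neighbourhood on the planar grid; disrupted maps update the BMU
// only.  Weight rule: w <- w + (alpha * h) * (x - w).
static void update_map(std::vector<double>& W, int rows, int cols, int dim,
                       const double* x, int bmu, double sigma_n, double alpha,
                       bool disrupted) {
  int brow = bmu / cols, bcol = bmu % cols;
  int n = rows * cols;
  double denom = 2.0 * (sigma_n * sigma_n);
  for (int i = 0; i < n; ++i) {
    double h;
    if (disrupted) {
      h = (i == bmu) ? 1.0 : 0.0;
      if (h == 0.0) continue;
    } else {
      int dr = (i / cols) - brow, dc = (i % cols) - bcol;
      double g2 = (double) (dr * dr + dc * dc);
      h = std::exp(-g2 / denom);
    }
    double coef = alpha * h;
    double* w = &W[(size_t) i * dim];
    for (int k = 0; k < dim; ++k) w[k] = w[k] + coef * (x[k] - w[k]);
  }
}

// Graded activation field: exp(-(d2 - d2_bmu) / (2 kappa^2)), normalised to
// sum one.  Subtracting the BMU distance keeps the exponent bounded (the
// normalised field is unchanged).
static void activation_field(const std::vector<double>& W, int n, int dim,
                             const double* x, double kappa,
                             std::vector<double>& act) {
  double denom = 2.0 * (kappa * kappa);
  double dmin = 0.0;
  std::vector<double> d2(n);
  for (int i = 0; i < n; ++i) {
    d2[i] = sqdist(x, &W[(size_t) i * dim], dim);
    if (i == 0 || d2[i] < dmin) dmin = d2[i];
  }
  long double s = 0.0L;
  for (int i = 0; i < n; ++i) {
    act[i] = std::exp(-(d2[i] - dmin) / denom);
    s += act[i];
  }
  double sd = (double) s;
  for (int i = 0; i < n; ++i) act[i] = act[i] / sd;
}

// out[j] = sum_i act[i] * B[i, j]  (aud -> vis uses B as stored; vis -> aud
// passes transpose = true).  Renormalised to sum one when the total mass is
// positive; an all-zero bridge yields the zero field (decoded as undefined).
static void propagate_field(const std::vector<double>& B, int na, int nv,
                            const std::vector<double>& act, bool transpose,
                            std::vector<double>& out) {
  int nout = transpose ? na : nv;
  long double tot = 0.0L;
  for (int j = 0; j < nout; ++j) {
    long double acc = 0.0L;
    if (transpose) {
      const double* row = &B[(size_t) j * nv];
      for (int v = 0; v < nv; ++v) acc += act[v] * row[v];
    } else {
      for (int a = 0; a < na; ++a) acc += act[a] * B[(size_t) a * nv + j];
    }
    out[j] = (double) acc;
    tot += out[j];
  }
  double td = (double) tot;
  if (td > 0.0) for (int j = 0; j < nout; ++j) out[j] = out[j] / td;
}

// winner = argmax of the field (lowest index on ties); category = nearest
// prototype to the winner's weight vector.  A flat field decodes to -1.
static int decode_field(const std::vector<double>& field, int n,
                        const std::vector<double>& W, int dim,
                        const NumericMatrix& proto) {
  double mx = field[0], mn = field[0];
  int win = 0;
  for (int i = 1; i < n; ++i) {
    if (field[i] > mx) { mx = field[i]; win = i; }
    if (field[i] < mn) mn = field[i];
  }
  if (mx - mn < 1e-15) return -1;
  int ncat = proto.nrow();
  const double* w = &W[(size_t) win * dim];
  int best = 0;
  double bestd = R_PosInf;
  for (int c = 0; c < ncat; ++c) {
    long double acc = 0.0L;
    for (int k = 0; k < dim; ++k) {
      double d = w[k] - proto(c, k);
      acc += d * d;
    }
    double dd = (double) acc;
    if (dd < bestd) { bestd = dd; best = c; }
  }
  return best;
}

// region-pooled decode: each neuron belongs to the category whose centroid
// is nearest to its weight vector; the decoded category is the one whose
// region carries the most propagated mass.  A flat field decodes to -1.
static void assign_regions(const std::vector<double>& W, int n, int dim,
                           const NumericMatrix& ref, std::vector<int>& region) {
  int ncat = ref.nrow();
  for (int i = 0; i < n; ++i) {
    const double* w = &W[(size_t) i * dim];
    int best = 0;
    double bestd = R_PosInf;
    for (int c = 0; c < ncat; ++c) {
      long double acc = 0.0L;
      for (int k = 0; k < dim; ++k) {
        double d = w[k] - ref(c, k);
        acc += d * d;
      }
      double dd = (double) acc;
      if (dd < bestd) { bestd = dd; best = c; }
    }
    region[i] = best;
  }
}

// centre-of-mass decode: the field's expected weight vector, then nearest
// centroid.  Reads out the whole distributed pattern (robust for diffuse
// fields) while staying in weight space, so cross-category bleed in the
// input field still degrades the readout.  A flat field decodes to -1.
static int decode_mass(const std::vector<double>& field, int n,
                       const std::vector<double>& W, int dim,
                       const NumericMatrix& ref) {
  double mx = field[0], mn = field[0];
  for (int i = 1; i < n; ++i) {
    if (field[i] > mx) mx = field[i];
    if (field[i] < mn) mn = field[i];
  }
  if (mx - mn < 1e-15) return -1;
  std::vector<double> wbar(dim);
  for (int k = 0; k < dim; ++k) {
    long double acc = 0.0L;
    for (int i = 0; i < n; ++i) acc += field[i] * W[(size_t) i * dim + k];
    wbar[k] = (double) acc;
  }
  int ncat = ref.nrow();
  int best = 0;
  double bestd = R_PosInf;
  for (int c = 0; c < ncat; ++c) {
    long double acc = 0.0L;
    for (int k = 0; k < dim; ++k) {
      double d = wbar[k] - ref(c, k);
      acc += d * d;
    }
    double dd = (double) acc;
    if (dd < bestd) { bestd = dd; best = c; }
  }
  return best;
}

static int decode_region(const std::vector<double>& field, int n,
                         const std::vector<int>& region, int ncat) {
  double mx = field[0], mn = field[0];
  for (int i = 1; i < n; ++i) {
    if (field[i] > mx) mx = field[i];
    if (field[i] < mn) mn = field[i];
  }
  if (mx - mn < 1e-15) return -1;
  std::vector<long double> mass(ncat, 0.0L);
  for (int i = 0; i < n; ++i) mass[region[i]] += field[i];
  int best = 0;
  double bestm = (double) mass[0];
  for (int c = 1; c < ncat; ++c) {
    double m = (double) mass[c];
    if (m > bestm) { bestm = m; best = c; }
  }
  return best;
}

// Fisher-Yates with R's unif_rand(); identical index arithmetic to the R
// engine so the two produce the same permutation from the same RNG state.
static void shuffle_idx(std::vector<int>& v) {
  int n = (int) v.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int) (unif_rand() * (i + 1));
    int tmp = v[i]; v[i] = v[j]; v[j] = tmp;
  }
}

static void add_noise(double* x, int dim, double sigma) {
  for (int k = 0; k < dim; ++k) {
    double z = x[k] + sigma * norm_rand();
    if (z < 0.0) z = 0.0; else if (z > 1.0) z = 1.0;
    x[k] = z;
  }
}

// One full training run: per epoch, shuffle the 160 paired presentations,
// re-pair auditory exemplars with same-category visual exemplars, train both
// maps and the Hebbian bridge, then test comprehension/production and record
// quantisation errors on the noise-free exemplar sets.
// [[Rcpp::export]]
List cpp_train_run(NumericMatrix aud_ex, NumericMatrix vis_ex,
                   IntegerVector ex_cat,
                   NumericMatrix aud_ref, NumericMatrix vis_ref,
                   NumericMatrix W_aud0, NumericMatrix W_vis0,
                   int aud_rows, int aud_cols, int vis_rows, int vis_cols,
                   double noise_aud, double noise_vis,
                   bool disrupt_aud, bool disrupt_vis,
                   int n_epochs, double lr_start, double lr_end,
                   double rad_start_aud, double rad_start_vis, double rad_end,
                   double eta, double kappa, int n_exemplars,
                   bool test_noise, bool exp_decay, int decode_mode) {
  RNGScope scope;
  const int dim = aud_ex.ncol();
  const int n_pat = aud_ex.nrow();
  const int ncat = aud_ref.nrow();
  const int na = aud_rows * aud_cols, nv = vis_rows * vis_cols;

  // neuron-major weight buffers
  std::vector<double> Wa((size_t) na * dim), Wv((size_t) nv * dim);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < dim; ++k) Wa[(size_t) i * dim + k] = W_aud0(i, k);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < dim; ++k) Wv[(size_t) i * dim + k] = W_vis0(i, k);

  std::vector<double> B((size_t) na * nv, 0.0);
  std::vector<double> xa(dim), xv(dim), act_a(na), act_v(nv);
  std::vector<double> field_a(na), field_v(nv);

  IntegerVector comp(n_epochs), prod(n_epochs);
  NumericVector qe_a(n_epochs), qe_v(n_epochs);
  // winners of every presentation in the final training epoch
  IntegerVector ep_bmu_a(n_epochs > 0 ? n_pat : 0),
                ep_bmu_v(n_epochs > 0 ? n_pat : 0);

  std::vector<int> order(n_pat);
  std::vector<int> perm(n_exemplars);

  for (int t = 0; t < n_epochs; ++t) {
    double frac = (n_epochs > 1) ? (double) t / (double) (n_epochs - 1) : 0.0;
    double alpha, sig_a, sig_v;
    if (exp_decay) {
      alpha = lr_start * std::pow(lr_end / lr_start, frac);
      sig_a = rad_start_aud * std::pow(rad_end / rad_start_aud, frac);
      sig_v = rad_start_vis * std::pow(rad_end / rad_start_vis, frac);
    } else {
      alpha = lr_start + (lr_end - lr_start) * frac;
      sig_a = rad_start_aud + (rad_end - rad_start_aud) * frac;
      sig_v = rad_start_vis + (rad_end - rad_start_vis) * frac;
    }

    for (int i = 0; i < n_pat; ++i) order[i] = i;
    shuffle_idx(order);

    // fresh within-category auditory-visual pairing each epoch
    std::vector<int> vis_of(n_pat);
    for (int c = 0; c < ncat; ++c) {
      for (int j = 0; j < n_exemplars; ++j) perm[j] = j;
      shuffle_idx(perm);
      for (int j = 0; j < n_exemplars; ++j)
        vis_of[c * n_exemplars + j] = c * n_exemplars + perm[j];
    }

    for (int p = 0; p < n_pat; ++p) {
      int e = order[p];
      int ev = vis_of[e];
      for (int k = 0; k < dim; ++k) xa[k] = aud_ex(e, k);
      for (int k = 0; k < dim; ++k) xv[k] = vis_ex(ev, k);
      if (noise_aud > 0.0) add_noise(&xa[0], dim, noise_aud);
      if (noise_vis > 0.0) add_noise(&xv[0], dim, noise_vis);

      int ba = bmu_of(Wa, na, dim, &xa[0], NULL);
      int bv = bmu_of(Wv, nv, dim, &xv[0], NULL);
      if (t == n_epochs - 1) { ep_bmu_a[p] = ba + 1; ep_bmu_v[p] = bv + 1; }
      update_map(Wa, aud_rows, aud_cols, dim, &xa[0], ba, sig_a, alpha,
                 disrupt_aud);
      update_map(Wv, vis_rows, vis_cols, dim, &xv[0], bv, sig_v, alpha,
                 disrupt_vis);

      activation_field(Wa, na, dim, &xa[0], kappa, act_a);
      activation_field(Wv, nv, dim, &xv[0], kappa, act_v);

      // Hebbian co-activation increment with divisive row normalisation:
      // any auditory row whose mass exceeds one is rescaled to sum one.
      for (int a = 0; a < na; ++a) {
        double* row = &B[(size_t) a * nv];
        double aa = act_a[a];
        for (int v = 0; v < nv; ++v) row[v] += eta * (aa * act_v[v]);
        long double rs = 0.0L;
        for (int v = 0; v < nv; ++v) rs += row[v];
        double rsd = (double) rs;
        if (rsd > 1.0)
          for (int v = 0; v < nv; ++v) row[v] = row[v] / rsd;
      }
    }

    // end-of-epoch lexical tests (noise-free unless test_noise)
    std::vector<int> region_a(na), region_v(nv);
    if (decode_mode == 1) {
      assign_regions(Wa, na, dim, aud_ref, region_a);
      assign_regions(Wv, nv, dim, vis_ref, region_v);
    }
    int ncomp = 0, nprod = 0;
    for (int c = 0; c < ncat; ++c) {
      int correct = 0;
      for (int j = 0; j < n_exemplars; ++j) {
        int e = c * n_exemplars + j;
        for (int k = 0; k < dim; ++k) xa[k] = aud_ex(e, k);
        if (test_noise && noise_aud > 0.0) add_noise(&xa[0], dim, noise_aud);
        activation_field(Wa, na, dim, &xa[0], kappa, act_a);
        propagate_field(B, na, nv, act_a, false, field_v);
        int dec = (decode_mode == 1)
          ? decode_region(field_v, nv, region_v, ncat)
          : (decode_mode == 2)
          ? decode_mass(field_v, nv, Wv, dim, vis_ref)
          : decode_field(field_v, nv, Wv, dim, vis_ref);
        if (dec == c) ++correct;
      }
      if (2 * correct > n_exemplars) ++ncomp;
    }
    for (int c = 0; c < ncat; ++c) {
      int correct = 0;
      for (int j = 0; j < n_exemplars; ++j) {
        int e = c * n_exemplars + j;
        for (int k = 0; k < dim; ++k) xv[k] = vis_ex(e, k);
        if (test_noise && noise_vis > 0.0) add_noise(&xv[0], dim, noise_vis);
        activation_field(Wv, nv, dim, &xv[0], kappa, act_v);
        propagate_field(B, na, nv, act_v, true, field_a);
        int dec = (decode_mode == 1)
          ? decode_region(field_a, na, region_a, ncat)
          : (decode_mode == 2)
          ? decode_mass(field_a, na, Wa, dim, aud_ref)
          : decode_field(field_a, na, Wa, dim, aud_ref);
        if (dec == c) ++correct;
      }
      if (2 * correct > n_exemplars) ++nprod;
    }
    comp[t] = ncomp;
    prod[t] = nprod;

    long double sa = 0.0L, sv = 0.0L;
    for (int e = 0; e < n_pat; ++e) {
      double d2;
      for (int k = 0; k < dim; ++k) xa[k] = aud_ex(e, k);
      bmu_of(Wa, na, dim, &xa[0], &d2);
      sa += std::sqrt(d2);
      for (int k = 0; k < dim; ++k) xv[k] = vis_ex(e, k);
      bmu_of(Wv, nv, dim, &xv[0], &d2);
      sv += std::sqrt(d2);
    }
    qe_a[t] = (double) sa / n_pat;
    qe_v[t] = (double) sv / n_pat;
  }

  // final BMU of every noise-free exemplar (for categorisation ratings)
  IntegerVector bmu_a_fin(n_pat), bmu_v_fin(n_pat);
  for (int e = 0; e < n_pat; ++e) {
    for (int k = 0; k < dim; ++k) xa[k] = aud_ex(e, k);
    bmu_a_fin[e] = bmu_of(Wa, na, dim, &xa[0], NULL) + 1;
    for (int k = 0; k < dim; ++k) xv[k] = vis_ex(e, k);
    bmu_v_fin[e] = bmu_of(Wv, nv, dim, &xv[0], NULL) + 1;
  }

  NumericMatrix Wa_out(na, dim), Wv_out(nv, dim), B_out(na, nv);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < dim; ++k) Wa_out(i, k) = Wa[(size_t) i * dim + k];
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < dim; ++k) Wv_out(i, k) = Wv[(size_t) i * dim + k];
  for (int a = 0; a < na; ++a)
    for (int v = 0; v < nv; ++v) B_out(a, v) = B[(size_t) a * nv + v];

  return List::create(_["comp"] = comp, _["prod"] = prod,
                      _["qe_aud"] = qe_a, _["qe_vis"] = qe_v,
                      _["W_aud"] = Wa_out, _["W_vis"] = Wv_out,
                      _["bridge"] = B_out,
                      _["bmu_aud"] = bmu_a_fin, _["bmu_vis"] = bmu_v_fin,
                      _["epoch_bmu_aud"] = ep_bmu_a,
                      _["epoch_bmu_vis"] = ep_bmu_v);
}
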