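#include <Rcpp.h>
using namespace Rcpp;

// Weighted 8-neighbour sum of a matrix: orthogonal neighbours count
// twice, diagonal neighbours once (the discrete diffusion stencil).
// Out-of-bounds neighbours contribute nothing.
// [[Rcpp::export(name = ".stencil_sum_cpp")]]
NumericMatrix stencil_sum_cpp(const NumericMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  const double* v = m.begin();
  double* o = out.begin();
  for (int j = 0; j < nc; ++j) {
    const double* c0 = v + (R_xlen_t)j * nr;
    const double* cl = j > 0 ? c0 - nr : nullptr;
    const double* cr = j < nc - 1 ? c0 + nr : nullptr;
    double* oc = o + (R_xlen_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      if (i > 0) acc += 2.0 * c0[i - 1];
      if (i < nr - 1) acc += 2.0 * c0[i + 1];
      if (cl) {
        acc += 2.0 * cl[i];
        if (i > 0) acc += cl[i - 1];
        if (i < nr - 1) acc += cl[i + 1];
      }
      if (cr) {
        acc += 2.0 * cr[i];
        if (i > 0) acc += cr[i - 1];
        if (i < nr - 1) acc += cr[i + 1];
      }
      oc[i] = acc;
    }
  }
  return out;
}

// One full explicit diffusion update of a signal field:
//   out = field * (1 - decay) + coef * (stencil(field) - field * wsum)
//         [+ alpha * dose]   then zeroed where the field is undefined.
// `wsum` is the precomputed weighted neighbour-permission sum and
// `defined` the 0/1 indicator of sites carrying the field; `coef` is
// w * dt / (4 d^2). `dose` may be an empty vector (no production).
// [[Rcpp::export(name = ".diffuse_cpp")]]
NumericMatrix diffuse_cpp(const NumericMatrix& field,
                          const NumericMatrix& wsum,
                          const NumericMatrix& defined,
                          double coef, double decay, double alpha,
                          const NumericVector& dose) {
  const int nr = field.nrow(), nc = field.ncol();
  const bool has_dose = dose.size() == (R_xlen_t)nr * nc;
  NumericMatrix out(nr, nc);
  const double* v = field.begin();
  const double* ws = wsum.begin();
  const double* df = defined.begin();
  const double* do_ = has_dose ? dose.begin() : nullptr;
  double* o = out.begin();
  const double keep = 1.0 - decay;
  for (int j = 0; j < nc; ++j) {
    const R_xlen_t off = (R_xlen_t)j * nr;
    const double* c0 = v + off;
    const double* cl = j > 0 ? c0 - nr : nullptr;
    const double* cr = j < nc - 1 ? c0 + nr : nullptr;
    for (int i = 0; i < nr; ++i) {
      const R_xlen_t k = off + i;
      if (df[k] == 0.0) { o[k] = 0.0; continue; }
      // neighbour values are gated by their own permission indicator so
      // that stray values on non-carrying sites can never leak in
      const double* d0 = df + off;
      const double* dl = cl ? d0 - nr : nullptr;
      const double* dr = cr ? d0 + nr : nullptr;
      double acc = 0.0;
      if (i > 0) acc += 2.0 * c0[i - 1] * d0[i - 1];
      if (i < nr - 1) acc += 2.0 * c0[i + 1] * d0[i + 1];
      if (cl) {
        acc += 2.0 * cl[i] * dl[i];
        if (i > 0) acc += cl[i - 1] * dl[i - 1];
        if (i < nr - 1) acc += cl[i + 1] * dl[i + 1];
      }
      if (cr) {
        acc += 2.0 * cr[i] * dr[i];
        if (i > 0) acc += cr[i - 1] * dr[i - 1];
        if (i < nr - 1) acc += cr[i + 1] * dr[i + 1];
      }
      double val = c0[i] * keep + coef * (acc - c0[i] * ws[k]);
      if (do_) val += alpha * do_[k];
      o[k] = val;
    }
  }
  return out;
}
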