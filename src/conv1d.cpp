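#include <Rcpp.h>
using namespace Rcpp;

// 1D valid convolution, stride 1, over activations a with dim (b, l, ch_in)
// and weights w with dim (k * ch_in, ch_out); column j = (ci - 1) * k + u
// maps to input offset u - 1 in channel ci.

// [[Rcpp::export]]
NumericVector conv1d_fwd(NumericVector a, NumericMatrix w, NumericVector bias,
                         int k) {
  IntegerVector d = a.attr("dim");
  const int b = d[0], l = d[1], ch_in = d[2];
  const int lo = l - k + 1;
  const int ch_out = w.ncol();
  NumericVector out(b * lo * ch_out);
  const double *pa = a.begin();
  double *po = out.begin();
  for (int co = 0; co < ch_out; ++co) {
    double *o = po + (R_xlen_t)co * b * lo;
    const double bv = bias[co];
    for (int i = 0; i < b * lo; ++i) o[i] = bv;
    for (int ci = 0; ci < ch_in; ++ci) {
      const double *ac = pa + (R_xlen_t)ci * b * l;
      for (int u = 0; u < k; ++u) {
        const double wv = w(ci * k + u, co);
        if (wv == 0.0) continue;
        for (int pos = 0; pos < lo; ++pos) {
          const double *ap = ac + (R_xlen_t)(pos + u) * b;
          double *op = o + (R_xlen_t)pos * b;
          for (int bb = 0; bb < b; ++bb) op[bb] += wv * ap[bb];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(b, lo, ch_out);
  return out;
}

// [[Rcpp::export]]
List conv1d_bwd(NumericVector dy, NumericVector a, NumericMatrix w, int k) {
  IntegerVector d = a.attr("dim");
  const int b = d[0], l = d[1], ch_in = d[2];
  const int lo = l - k + 1;
  const int ch_out = w.ncol();
  NumericMatrix dw(k * ch_in, ch_out);
  NumericVector db(ch_out);
  NumericVector da(b * l * ch_in);
  const double *pa = a.begin();
  const double *pdy = dy.begin();
  double *pda = da.begin();
  for (int co = 0; co < ch_out; ++co) {
    const double *dyc = pdy + (R_xlen_t)co * b * lo;
    double acc = 0.0;
    for (int i = 0; i < b * lo; ++i) acc += dyc[i];
    db[co] = acc;
    for (int ci = 0; ci < ch_in; ++ci) {
      const double *ac = pa + (R_xlen_t)ci * b * l;
      double *dac = pda + (R_xlen_t)ci * b * l;
      for (int u = 0; u < k; ++u) {
        const double wv = w(ci * k + u, co);
        double g = 0.0;
        for (int pos = 0; pos < lo; ++pos) {
          const double *ap = ac + (R_xlen_t)(pos + u) * b;
          const double *dp = dyc + (R_xlen_t)pos * b;
          double *dap = dac + (R_xlen_t)(pos + u) * b;
          for (int bb = 0; bb < b; ++bb) {
            g += ap[bb] * dp[bb];
            dap[bb] += wv * dp[bb];
          }
        }
        dw(ci * k + u, co) = g;
      }
    }
  }
  da.attr("dim") = IntegerVector::create(b, l, ch_in);
  return List::create(_["da"] = da, _["dw"] = dw, _["db"] = db);
}

// max pooling of size p along the length axis (valid windows only)

// [[Rcpp::export]]
List maxpool1d_fwd(NumericVector a, int p) {
  IntegerVector d = a.attr("dim");
  const int b = d[0], l = d[1], ch = d[2];
  const int lw = l / p;
  NumericVector out(b * lw * ch);
  IntegerVector arg(b * lw * ch);
  const double *pa = a.begin();
  double *po = out.begin();
  int *pg = arg.begin();
  for (int c = 0; c < ch; ++c) {
    const double *ac = pa + (R_xlen_t)c * b * l;
    double *oc = po + (R_xlen_t)c * b * lw;
    int *gc = pg + (R_xlen_t)c * b * lw;
    for (int wdx = 0; wdx < lw; ++wdx) {
      for (int bb = 0; bb < b; ++bb) {
        double best = ac[(R_xlen_t)(wdx * p) * b + bb];
        int besti = 0;
        for (int v = 1; v < p; ++v) {
          double x = ac[(R_xlen_t)(wdx * p + v) * b + bb];
          if (x > best) { best = x; besti = v; }
        }
        oc[(R_xlen_t)wdx * b + bb] = best;
        gc[(R_xlen_t)wdx * b + bb] = besti;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(b, lw, ch);
  arg.attr("dim") = IntegerVector::create(b, lw, ch);
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool1d_bwd(NumericVector dy, IntegerVector arg, int l, int p) {
  IntegerVector d = dy.attr("dim");
  const int b = d[0], lw = d[1], ch = d[2];
  NumericVector da(b * l * ch);
  const double *pdy = dy.begin();
  const int *pg = arg.begin();
  double *pda = da.begin();
  for (int c = 0; c < ch; ++c) {
    const double *dyc = pdy + (R_xlen_t)c * b * lw;
    const int *gc = pg + (R_xlen_t)c * b * lw;
    double *dac = pda + (R_xlen_t)c * b * l;
    for (int wdx = 0; wdx < lw; ++wdx) {
      for (int bb = 0; bb < b; ++bb) {
        int v = gc[(R_xlen_t)wdx * b + bb];
        dac[(R_xlen_t)(wdx * p + v) * b + bb] = dyc[(R_xlen_t)wdx * b + bb];
      }
    }
  }
  da.attr("dim") = IntegerVector::create(b, l, ch);
  return da;
}

// im2col gather: a (b, l, ch) -> matrix (b*lo, k*ch) whose column
// j = (ci - 1) * k + u holds a[, (u:(u+lo-1)) + ...,  ci]; the convolution
// then becomes one BLAS matmul.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector a, int k) {
  IntegerVector d = a.attr("dim");
  const int b = d[0], l = d[1], ch = d[2];
  const int lo = l - k + 1;
  NumericMatrix out(b * lo, k * ch);
  const double *pa = a.begin();
  double *po = out.begin();
  for (int ci = 0; ci < ch; ++ci) {
    const double *ac = pa + (R_xlen_t)ci * b * l;
    for (int u = 0; u < k; ++u) {
      double *oc = po + (R_xlen_t)(ci * k + u) * b * lo;
      for (int pos = 0; pos < lo; ++pos) {
        std::memcpy(oc + (R_xlen_t)pos * b, ac + (R_xlen_t)(pos + u) * b,
                    b * sizeof(double));
      }
    }
  }
  return out;
}
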