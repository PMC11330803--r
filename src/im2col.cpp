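#include <Rcpp.h>
using namespace Rcpp;

// im2col gather: padded feature maps Xp ((B*npad) x C) and a 0-based index
// table idx (length B*nout*9, tap-major blocks) produce the patch matrix
// (B*nout) x (9*C) with column (c * 9 + k) holding tap k of channel c.
// [[Rcpp::export(name = ".im2col_cpp")]]
NumericMatrix im2col_cpp(NumericMatrix Xp, IntegerVector idx, int nout) {
  const int C = Xp.ncol();
  NumericMatrix out(nout, 9 * C);
  const double* xp = Xp.begin();
  const int* id = idx.begin();
  const R_xlen_t nrow_xp = Xp.nrow();
  double* o = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* col = xp + (R_xlen_t)c * nrow_xp;
    for (int k = 0; k < 9; ++k) {
      double* dst = o + ((R_xlen_t)(c * 9 + k)) * nout;
      const int* src = id + (R_xlen_t)k * nout;
      for (int r = 0; r < nout; ++r) dst[r] = col[src[r]];
    }
  }
  return out;
}

// Zero-pad feature maps: scatter X ((B*npix) x C) into a (B*npad) x C matrix
// at the given 0-based interior row positions.
// [[Rcpp::export(name = ".pad_maps_cpp")]]
NumericMatrix pad_maps_cpp(NumericMatrix X, IntegerVector interior, int npad_total) {
  const int C = X.ncol();
  const int n = X.nrow();
  NumericMatrix out(npad_total, C);
  const double* x = X.begin();
  const int* in = interior.begin();
  double* o = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* src = x + (R_xlen_t)c * n;
    double* dst = o + (R_xlen_t)c * npad_total;
    for (int r = 0; r < n; ++r) dst[in[r]] = src[r];
  }
  return out;
}

// col2im scatter-add: patch-gradient matrix dcols ((B*nout) x (9*C)) is
// accumulated back onto the padded map it was gathered from, then the
// interior rows are extracted. idx is the same 0-based gather table used by
// im2col; interior the 0-based padded positions of the unpadded pixels.
// [[Rcpp::export(name = ".col2im_cpp")]]
NumericMatrix col2im_cpp(NumericMatrix dcols, IntegerVector idx,
                         int npad_total, IntegerVector interior) {
  const int C = dcols.ncol() / 9;
  const int nout = dcols.nrow();
  const int n_in = interior.size();
  NumericMatrix acc(npad_total, C);
  NumericMatrix out(n_in, C);
  const double* dc = dcols.begin();
  const int* id = idx.begin();
  const int* in = interior.begin();
  double* a = acc.begin();
  for (int c = 0; c < C; ++c) {
    double* accc = a + (R_xlen_t)c * npad_total;
    for (int k = 0; k < 9; ++k) {
      const double* src = dc + ((R_xlen_t)(c * 9 + k)) * nout;
      const int* ix = id + (R_xlen_t)k * nout;
      for (int r = 0; r < nout; ++r) accc[ix[r]] += src[r];
    }
    double* o = out.begin() + (R_xlen_t)c * n_in;
    for (int r = 0; r < n_in; ++r) o[r] = accc[in[r]];
  }
  return out;
}

// Fused ConvLSTM gate evaluation: Zx, Zh are the input- and recurrent-path
// pre-activations ((n) x (4H), gate blocks i|f|o|g), b the bias (4H),
// Cprev the previous cell map (n x H). Returns the gate maps and updated
// state in one pass.
// [[Rcpp::export(name = ".lstm_gates_fwd_cpp")]]
List lstm_gates_fwd_cpp(NumericMatrix Zx, NumericMatrix Zh,
                        NumericVector b, NumericMatrix Cprev) {
  const int n = Zx.nrow();
  const int H = Cprev.ncol();
  NumericMatrix i_(n, H), f_(n, H), o_(n, H), g_(n, H), C(n, H), tC(n, H),
      Hn(n, H);
  const double *zx = Zx.begin(), *zh = Zh.begin(), *cp = Cprev.begin();
  const double *bp = b.begin();
  double *pi = i_.begin(), *pf = f_.begin(), *po = o_.begin(),
         *pg = g_.begin(), *pc = C.begin(), *pt = tC.begin(),
         *ph = Hn.begin();
  for (int h = 0; h < H; ++h) {
    const R_xlen_t off = (R_xlen_t)h * n;
    const double bi = bp[h], bf = bp[H + h], bo = bp[2 * H + h],
                 bg = bp[3 * H + h];
    const double *zxi = zx + off, *zhi = zh + off;
    const double *zxf = zx + (R_xlen_t)(H + h) * n,
                 *zhf = zh + (R_xlen_t)(H + h) * n;
    const double *zxo = zx + (R_xlen_t)(2 * H + h) * n,
                 *zho = zh + (R_xlen_t)(2 * H + h) * n;
    const double *zxg = zx + (R_xlen_t)(3 * H + h) * n,
                 *zhg = zh + (R_xlen_t)(3 * H + h) * n;
    const double *cph = cp + off;
    for (int r = 0; r < n; ++r) {
      const double iv = 1.0 / (1.0 + std::exp(-(zxi[r] + zhi[r] + bi)));
      const double fv = 1.0 / (1.0 + std::exp(-(zxf[r] + zhf[r] + bf)));
      const double ov = 1.0 / (1.0 + std::exp(-(zxo[r] + zho[r] + bo)));
      const double gv = std::tanh(zxg[r] + zhg[r] + bg);
      const double cv = fv * cph[r] + iv * gv;
      const double tv = std::tanh(cv);
      pi[off + r] = iv; pf[off + r] = fv; po[off + r] = ov; pg[off + r] = gv;
      pc[off + r] = cv; pt[off + r] = tv; ph[off + r] = ov * tv;
    }
  }
  return List::create(_["i"] = i_, _["f"] = f_, _["o"] = o_, _["g"] = g_,
                      _["C"] = C, _["tC"] = tC, _["H"] = Hn);
}

// Fused ConvLSTM gate backward: given dH_t (n x H), incoming cell gradient
// dC_in (n x H, may be 0 x 0 for none) and the cached gate/state maps,
// produce the pre-activation gradient dZ (n x 4H) and the cell gradient
// passed to step t-1.
// [[Rcpp::export(name = ".lstm_gates_bwd_cpp")]]
List lstm_gates_bwd_cpp(NumericMatrix dHt, NumericMatrix dC_in,
                        NumericMatrix i_, NumericMatrix f_, NumericMatrix o_,
                        NumericMatrix g_, NumericMatrix Cprev,
                        NumericMatrix tC) {
  const int n = dHt.nrow();
  const int H = dHt.ncol();
  const bool has_dc = dC_in.nrow() == n;
  NumericMatrix dZ(n, 4 * H), dCp(n, H);
  const double *dh = dHt.begin(), *dci = dC_in.begin(), *pi = i_.begin(),
               *pf = f_.begin(), *po = o_.begin(), *pg = g_.begin(),
               *cp = Cprev.begin(), *pt = tC.begin();
  double *dz = dZ.begin(), *dcp = dCp.begin();
  for (int h = 0; h < H; ++h) {
    const R_xlen_t off = (R_xlen_t)h * n;
    double *dzi = dz + off, *dzf = dz + (R_xlen_t)(H + h) * n,
           *dzo = dz + (R_xlen_t)(2 * H + h) * n,
           *dzg = dz + (R_xlen_t)(3 * H + h) * n;
    for (int r = 0; r < n; ++r) {
      const double dhv = dh[off + r];
      const double ov = po[off + r], tv = pt[off + r], iv = pi[off + r],
                   fv = pf[off + r], gv = pg[off + r];
      double dc = dhv * ov * (1.0 - tv * tv);
      if (has_dc) dc += dci[off + r];
      dzi[r] = dc * gv * iv * (1.0 - iv);
      dzf[r] = dc * cp[off + r] * fv * (1.0 - fv);
      dzo[r] = dhv * tv * ov * (1.0 - ov);
      dzg[r] = dc * iv * (1.0 - gv * gv);
      dcp[off + r] = dc * fv;
    }
  }
  return List::create(_["dZ"] = dZ, _["dC_prev"] = dCp);
}
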