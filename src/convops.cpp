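// Minimal conv / transposed-conv primitives for the patch autoencoder.
// Images are arma::cube(h, w, channels); batches are R 4-D arrays
// dim = c(h, w, channels, n) in column-major order, which maps directly
// onto a sequence of cubes. Convolutions are im2col + GEMM; the
// transposed convolution is the exact adjoint (col2im + GEMM), so the
// backward passes reuse the same two primitives with roles swapped.
//
// Weight layout: conv weights are R arrays dim c(k, k, c_in, c_out);
// flattened column-major this matches the im2col row ordering
// r = ki + k*kj + k*k*c. Transposed-conv weights are dim
// c(k, k, c_out, c_in) (c_out = channels of the larger output image).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col(const cube& x, int k, int stride, int pad, int ho, int wo) {
    const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
    mat cols(k * k * cin, ho * wo, fill::zeros);
    for (int c = 0; c < cin; ++c) {
        for (int kj = 0; kj < k; ++kj) {
            for (int ki = 0; ki < k; ++ki) {
                const int r = ki + k * kj + k * k * c;
                for (int oj = 0; oj < wo; ++oj) {
                    const int jj = oj * stride + kj - pad;
                    if (jj < 0 || jj >= w) continue;
                    for (int oi = 0; oi < ho; ++oi) {
                        const int ii = oi * stride + ki - pad;
                        if (ii < 0 || ii >= h) continue;
                        cols(r, oi + ho * oj) = x(ii, jj, c);
                    }
                }
            }
        }
    }
    return cols;
}

// Adjoint of im2col: scatter-add columns back into an image of
// size h x w x cin; (ho, wo) is the sliding-window grid the columns
// were (or would have been) gathered over.
static cube col2im(const mat& cols, int h, int w, int cin,
                   int k, int stride, int pad, int ho, int wo) {
    cube x(h, w, cin, fill::zeros);
    for (int c = 0; c < cin; ++c) {
        for (int kj = 0; kj < k; ++kj) {
            for (int ki = 0; ki < k; ++ki) {
                const int r = ki + k * kj + k * k * c;
                for (int oj = 0; oj < wo; ++oj) {
                    const int jj = oj * stride + kj - pad;
                    if (jj < 0 || jj >= w) continue;
                    for (int oi = 0; oi < ho; ++oi) {
                        const int ii = oi * stride + ki - pad;
                        if (ii < 0 || ii >= h) continue;
                        x(ii, jj, c) += cols(r, oi + ho * oj);
                    }
                }
            }
        }
    }
    return x;
}

static cube slice4d(const Rcpp::NumericVector& x, const Rcpp::IntegerVector& d, int n) {
    // view image n of a (h, w, c, n) array as a cube (copy)
    const int sz = d[0] * d[1] * d[2];
    cube out(d[0], d[1], d[2]);
    std::copy(x.begin() + (R_xlen_t)n * sz, x.begin() + (R_xlen_t)(n + 1) * sz,
              out.memptr());
    return out;
}

static Rcpp::NumericVector alloc4d(int h, int w, int c, int n) {
    Rcpp::NumericVector out((R_xlen_t)h * w * c * n);
    out.attr("dim") = Rcpp::IntegerVector::create(h, w, c, n);
    return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv_forward(Rcpp::NumericVector x, Rcpp::NumericVector w,
                                     Rcpp::NumericVector b, int stride, int pad) {
    Rcpp::IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
    const int h = dx[0], wd = dx[1], cin = dx[2], n = dx[3];
    const int k = dw[0], cout = dw[3];
    if (dw[2] != cin) Rcpp::stop("channel mismatch between input and weights");
    const int ho = (h + 2 * pad - k) / stride + 1;
    const int wo = (wd + 2 * pad - k) / stride + 1;
    const mat W(const_cast<double*>(w.begin()), k * k * cin, cout, false, true);
    const vec bias(const_cast<double*>(b.begin()), cout, false, true);

    Rcpp::NumericVector out = alloc4d(ho, wo, cout, n);
    const int sz = ho * wo * cout;
    for (int img = 0; img < n; ++img) {
        cube xi = slice4d(x, dx, img);
        mat cols = im2col(xi, k, stride, pad, ho, wo);
        mat y = W.t() * cols;          // cout x (ho*wo)
        y.each_col() += bias;
        // y row c, column l = oi + ho*oj  ->  out[oi, oj, c, img]
        double* optr = out.begin() + (R_xlen_t)img * sz;
        for (int c = 0; c < cout; ++c)
            for (int l = 0; l < ho * wo; ++l)
                optr[l + c * ho * wo] = y(c, l);
    }
    return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(Rcpp::NumericVector x, Rcpp::NumericVector w,
                             Rcpp::NumericVector dy, int stride, int pad) {
    Rcpp::IntegerVector dx_ = x.attr("dim"), dw_ = w.attr("dim"), dd = dy.attr("dim");
    const int h = dx_[0], wd = dx_[1], cin = dx_[2], n = dx_[3];
    const int k = dw_[0], cout = dw_[3];
    const int ho = dd[0], wo = dd[1];
    const mat W(const_cast<double*>(w.begin()), k * k * cin, cout, false, true);

    Rcpp::NumericVector dxo = alloc4d(h, wd, cin, n);
    mat dW(k * k * cin, cout, fill::zeros);
    vec db(cout, fill::zeros);
    const int szx = h * wd * cin, szy = ho * wo * cout;
    for (int img = 0; img < n; ++img) {
        cube xi = slice4d(x, dx_, img);
        mat cols = im2col(xi, k, stride, pad, ho, wo);
        // reconstruct dY as cout x L from the 4-D slice
        mat dY(cout, ho * wo);
        const double* dptr = dy.begin() + (R_xlen_t)img * szy;
        for (int c = 0; c < cout; ++c)
            for (int l = 0; l < ho * wo; ++l)
                dY(c, l) = dptr[l + c * ho * wo];
        dW += cols * dY.t();
        db += sum(dY, 1);
        cube dxi = col2im(W * dY, h, wd, cin, k, stride, pad, ho, wo);
        std::copy(dxi.memptr(), dxi.memptr() + szx, dxo.begin() + (R_xlen_t)img * szx);
    }
    Rcpp::NumericVector dWo(dW.memptr(), dW.memptr() + dW.n_elem);
    dWo.attr("dim") = dw_;
    return Rcpp::List::create(Rcpp::Named("dx") = dxo,
                              Rcpp::Named("dw") = dWo,
                              Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_tconv_forward(Rcpp::NumericVector x, Rcpp::NumericVector w,
                                      Rcpp::NumericVector b, int stride, int pad) {
    Rcpp::IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
    const int h = dx[0], wd = dx[1], cin = dx[2], n = dx[3];
    const int k = dw[0], cout = dw[2];
    if (dw[3] != cin) Rcpp::stop("channel mismatch between input and weights");
    const int ho = (h - 1) * stride - 2 * pad + k;
    const int wo = (wd - 1) * stride - 2 * pad + k;
    const mat V(const_cast<double*>(w.begin()), k * k * cout, cin, false, true);
    const vec bias(const_cast<double*>(b.begin()), cout, false, true);

    Rcpp::NumericVector out = alloc4d(ho, wo, cout, n);
    const int szy = ho * wo * cout;
    for (int img = 0; img < n; ++img) {
        cube xi = slice4d(x, dx, img);
        mat X(cin, h * wd);
        for (int c = 0; c < cin; ++c)
            X.row(c) = vectorise(xi.slice(c)).t();
        cube y = col2im(V * X, ho, wo, cout, k, stride, pad, h, wd);
        for (int c = 0; c < cout; ++c) y.slice(c) += bias(c);
        std::copy(y.memptr(), y.memptr() + szy, out.begin() + (R_xlen_t)img * szy);
    }
    return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_tconv_backward(Rcpp::NumericVector x, Rcpp::NumericVector w,
                              Rcpp::NumericVector dy, int stride, int pad) {
    Rcpp::IntegerVector dx_ = x.attr("dim"), dw_ = w.attr("dim"), dd = dy.attr("dim");
    const int h = dx_[0], wd = dx_[1], cin = dx_[2], n = dx_[3];
    const int k = dw_[0], cout = dw_[2];
    const int ho = dd[0], wo = dd[1];
    const mat V(const_cast<double*>(w.begin()), k * k * cout, cin, false, true);

    Rcpp::NumericVector dxo = alloc4d(h, wd, cin, n);
    mat dV(k * k * cout, cin, fill::zeros);
    vec db(cout, fill::zeros);
    const int szx = h * wd * cin;
    for (int img = 0; img < n; ++img) {
        cube dyi = slice4d(dy, dd, img);
        for (int c = 0; c < cout; ++c) db(c) += accu(dyi.slice(c));
        mat dy_cols = im2col(dyi, k, stride, pad, h, wd);
        cube xi = slice4d(x, dx_, img);
        mat X(cin, h * wd);
        for (int c = 0; c < cin; ++c)
            X.row(c) = vectorise(xi.slice(c)).t();
        dV += dy_cols * X.t();
        mat dX = V.t() * dy_cols;       // cin x (h*wd)
        double* dptr = dxo.begin() + (R_xlen_t)img * szx;
        for (int c = 0; c < cin; ++c)
            for (int l = 0; l < h * wd; ++l)
                dptr[l + c * h * wd] = dX(c, l);
    }
    Rcpp::NumericVector dVo(dV.memptr(), dV.memptr() + dV.n_elem);
    dVo.attr("dim") = dw_;
    return Rcpp::List::create(Rcpp::Named("dx") = dxo,
                              Rcpp::Named("dw") = dVo,
                              Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()));
}
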