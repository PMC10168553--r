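// Low-level numerical kernels: minimal CNN layer primitives (im2col + GEMM
// convolution, 2x2 max-pooling, nearest-neighbour upsampling), image filters
// with symmetric padding, affine warping, connected components, flood fill,
// seeded region growing and boundary Hausdorff distance.
//
// Array convention: R arrays of dim (H, W, C, N), column-major, H fastest.
// Weight matrices: (Cout x K) with K = C*kh*kw and column index
// j = c*kh*kw + ki*kw + kj (0-based); spatial offsets (ki - pad, kj - pad).

#include <RcppArmadillo.h>
#include <queue>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // symmetric padding (edge pixel repeated): ... 1 0 | 0 1 2 ... n-1 | n-1 n-2 ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static void im2col_f(const double* x, int H, int W, int C,
                     int kh, int kw, int pad, arma::fmat& col) {
  const int HW = H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * HW;
    for (int ki = 0; ki < kh; ++ki) {
      for (int kj = 0; kj < kw; ++kj) {
        const int r = c * kh * kw + ki * kw + kj;
        const int di = ki - pad, dj = kj - pad;
        float* crow = col.memptr() + r;  // stride = col.n_rows
        const int K = col.n_rows;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dj;
          if (sw < 0 || sw >= W) {
            for (int h = 0; h < H; ++h) crow[(size_t)K * (h + H * w)] = 0.0f;
          } else {
            const double* src = xc + (size_t)H * sw;
            for (int h = 0; h < H; ++h) {
              const int sh = h + di;
              crow[(size_t)K * (h + H * w)] =
                (sh < 0 || sh >= H) ? 0.0f : (float)src[sh];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, IntegerVector dims,
                         NumericMatrix Wm, NumericVector b,
                         int kh, int kw, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Cout = Wm.nrow(), K = Wm.ncol();
  if (K != C * kh * kw) stop("weight shape mismatch");
  const int HW = H * W;
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::fmat Wf(Cout, K);
  for (int j = 0; j < K; ++j)
    for (int i = 0; i < Cout; ++i) Wf(i, j) = (float)Wm(i, j);
  arma::fvec bf(Cout);
  for (int i = 0; i < Cout; ++i) bf(i) = (float)b[i];
  arma::fmat col(K, HW);
  for (int n = 0; n < N; ++n) {
    im2col_f(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, pad, col);
    arma::fmat Y = Wf * col;
    Y.each_col() += bf;
    double* yp = y.begin() + (size_t)n * HW * Cout;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < HW; ++p) yp[(size_t)co * HW + p] = Y(co, p);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, IntegerVector dims,
                NumericMatrix Wm, NumericVector dy,
                int kh, int kw, int pad) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Cout = Wm.nrow(), K = Wm.ncol();
  const int HW = H * W;
  arma::fmat Wf(Cout, K);
  for (int j = 0; j < K; ++j)
    for (int i = 0; i < Cout; ++i) Wf(i, j) = (float)Wm(i, j);
  arma::fmat dW(Cout, K, arma::fill::zeros);
  arma::fvec db(Cout, arma::fill::zeros);
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  arma::fmat col(K, HW), dyM(Cout, HW);
  for (int n = 0; n < N; ++n) {
    im2col_f(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, pad, col);
    const double* dyp = dy.begin() + (size_t)n * HW * Cout;
    for (int co = 0; co < Cout; ++co)
      for (int p = 0; p < HW; ++p) dyM(co, p) = (float)dyp[(size_t)co * HW + p];
    dW += dyM * col.t();
    db += arma::sum(dyM, 1);
    arma::fmat dcol = Wf.t() * dyM;  // K x HW
    double* dxp = dx.begin() + (size_t)n * HW * C;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxp + (size_t)c * HW;
      for (int ki = 0; ki < kh; ++ki) {
        for (int kj = 0; kj < kw; ++kj) {
          const int r = c * kh * kw + ki * kw + kj;
          const int di = ki - pad, dj = kj - pad;
          for (int w = 0; w < W; ++w) {
            const int sw = w + dj;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              const int sh = h + di;
              if (sh < 0 || sh >= H) continue;
              dxc[sh + (size_t)H * sw] += dcol(r, h + H * w);
            }
          }
        }
      }
    }
  }
  NumericMatrix dWr(Cout, K);
  for (int j = 0; j < K; ++j)
    for (int i = 0; i < Cout; ++i) dWr(i, j) = dW(i, j);
  NumericVector dbr(Cout);
  for (int i = 0; i < Cout; ++i) dbr[i] = db(i);
  return List::create(_["dx"] = dx, _["dW"] = dWr, _["db"] = dbr);
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h, ++o) {
          size_t best = base + (size_t)(2 * h) + (size_t)H * (2 * w);
          double bv = xp[best];
          const int dh[3] = {1, 0, 1}, dw[3] = {0, 1, 1};
          for (int t = 0; t < 3; ++t) {
            size_t i2 = base + (size_t)(2 * h + dh[t]) + (size_t)H * (2 * w + dw[t]);
            if (xp[i2] > bv) { bv = xp[i2]; best = i2; }
          }
          // column-major output order is h fastest, matching o only if we
          // iterate h innermost per (w, c, n) — but o must follow R layout:
          // linear index = h + Ho*(w + Wo*(c + C*n)); our loop nest is
          // n, c, w, h which matches that order apart from h/w swap.
          size_t oi = (size_t)h + (size_t)Ho * (w + (size_t)Wo * (c + (size_t)C * n));
          yp[oi] = bv;
          idx[oi] = (int)best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(IntegerVector idx, NumericVector dy, int xlen) {
  NumericVector dx(xlen);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = xp[bi + h + (size_t)H * w];
          yp[bo + 2 * h + (size_t)Ho * (2 * w)] = v;
          yp[bo + 2 * h + 1 + (size_t)Ho * (2 * w)] = v;
          yp[bo + 2 * h + (size_t)Ho * (2 * w + 1)] = v;
          yp[bo + 2 * h + 1 + (size_t)Ho * (2 * w + 1)] = v;
        }
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector dy, IntegerVector dims) {
  // dims are the dims of dy (2H, 2W, C, N)
  const int Ho = dims[0], Wo = dims[1], C = dims[2], N = dims[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      const size_t bi = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          dxp[bi + h + (size_t)H * w] =
            dyp[bo + 2 * h + (size_t)Ho * (2 * w)] +
            dyp[bo + 2 * h + 1 + (size_t)Ho * (2 * w)] +
            dyp[bo + 2 * h + (size_t)Ho * (2 * w + 1)] +
            dyp[bo + 2 * h + 1 + (size_t)Ho * (2 * w + 1)];
        }
    }
  return dx;
}

// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix m, int kh, int kw) {
  // even kernels take offsets -(k-1)/2 .. +k/2; symmetric (reflect) padding;
  // median of an even count is the mean of the two middle order statistics
  const int H = m.nrow(), W = m.ncol();
  NumericMatrix out(H, W);
  const int lo_i = -(kh - 1) / 2, hi_i = kh / 2;
  const int lo_j = -(kw - 1) / 2, hi_j = kw / 2;
  std::vector<double> buf((size_t)kh * kw);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      size_t t = 0;
      for (int dj = lo_j; dj <= hi_j; ++dj) {
        const int cj = reflect_idx(j + dj, W);
        for (int di = lo_i; di <= hi_i; ++di)
          buf[t++] = m(reflect_idx(i + di, H), cj);
      }
      const size_t nmid = t / 2;
      std::nth_element(buf.begin(), buf.begin() + nmid, buf.begin() + t);
      double med = buf[nmid];
      if (t % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + nmid);
        med = 0.5 * (lo + med);
      }
      out(i, j) = med;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix filter_kernel_cpp(NumericMatrix m, NumericMatrix kern) {
  // correlation with symmetric (reflect) padding; odd kernel centred
  const int H = m.nrow(), W = m.ncol();
  const int kh = kern.nrow(), kw = kern.ncol();
  const int ci = kh / 2, cj = kw / 2;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int dj = 0; dj < kw; ++dj) {
        const int sj = reflect_idx(j + dj - cj, W);
        for (int di = 0; di < kh; ++di)
          s += kern(di, dj) * m(reflect_idx(i + di - ci, H), sj);
      }
      out(i, j) = s;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix warp_affine_cpp(NumericMatrix m, NumericVector inv,
                              int nearest) {
  // inverse mapping: src = A %*% dst + t in 0-based (row, col) coordinates;
  // inv = (a11, a12, a21, a22, t1, t2); zero fill outside the source grid
  const int H = m.nrow(), W = m.ncol();
  const double a11 = inv[0], a12 = inv[1], a21 = inv[2], a22 = inv[3];
  const double t1 = inv[4], t2 = inv[5];
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double sr = a11 * i + a12 * j + t1;
      const double sc = a21 * i + a22 * j + t2;
      if (nearest) {
        const int ri = (int)std::floor(sr + 0.5);
        const int ci = (int)std::floor(sc + 0.5);
        out(i, j) = (ri < 0 || ri >= H || ci < 0 || ci >= W) ? 0.0 : m(ri, ci);
      } else {
        const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
        const double fr = sr - r0, fc = sc - c0;
        double v = 0.0;
        for (int dr = 0; dr <= 1; ++dr)
          for (int dc = 0; dc <= 1; ++dc) {
            const int rr = r0 + dr, cc = c0 + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            const double wgt = (dr ? fr : 1.0 - fr) * (dc ? fc : 1.0 - fc);
            v += wgt * m(rr, cc);
          }
        out(i, j) = v;
      }
    }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix label8_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(i + H * j);
      while (!q.empty()) {
        const int p = q.front(); q.pop();
        const int pi = p % H, pj = p / H;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            const int ni = pi + di, nj = pj + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(ni + H * nj);
            }
          }
      }
    }
  return lab;
}

// [[Rcpp::export]]
IntegerMatrix flood_border_cpp(IntegerMatrix blocked) {
  // 4-connected reachability from the image border through blocked == 0
  const int H = blocked.nrow(), W = blocked.ncol();
  IntegerMatrix reached(H, W);
  std::queue<int> q;
  auto push = [&](int i, int j) {
    if (blocked(i, j) == 0 && reached(i, j) == 0) {
      reached(i, j) = 1;
      q.push(i + H * j);
    }
  };
  for (int i = 0; i < H; ++i) { push(i, 0); push(i, W - 1); }
  for (int j = 0; j < W; ++j) { push(0, j); push(H - 1, j); }
  const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    const int p = q.front(); q.pop();
    const int pi = p % H, pj = p / H;
    for (int t = 0; t < 4; ++t) {
      const int ni = pi + di[t], nj = pj + dj[t];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      push(ni, nj);
    }
  }
  return reached;
}

// [[Rcpp::export]]
IntegerMatrix region_grow_cpp(NumericMatrix score, IntegerMatrix allowed,
                              int seed_r, int seed_c, int target) {
  // seeded priority flood: repeatedly annex the frontier pixel (4-connected)
  // with the highest score until the region reaches `target` pixels
  const int H = score.nrow(), W = score.ncol();
  IntegerMatrix region(H, W);
  if (target <= 0 || allowed(seed_r, seed_c) == 0) return region;
  typedef std::pair<double, int> PQE;
  std::priority_queue<PQE> pq;
  IntegerMatrix seen(H, W);
  pq.push(PQE(score(seed_r, seed_c), seed_r + H * seed_c));
  seen(seed_r, seed_c) = 1;
  int n = 0;
  const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
  while (!pq.empty() && n < target) {
    const int p = pq.top().second; pq.pop();
    const int pi = p % H, pj = p / H;
    region(pi, pj) = 1;
    ++n;
    for (int t = 0; t < 4; ++t) {
      const int ni = pi + di[t], nj = pj + dj[t];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      if (allowed(ni, nj) != 0 && seen(ni, nj) == 0) {
        seen(ni, nj) = 1;
        pq.push(PQE(score(ni, nj), ni + H * nj));
      }
    }
  }
  return region;
}

static std::vector<std::pair<int,int> > boundary_points(const IntegerMatrix& m) {
  const int H = m.nrow(), W = m.ncol();
  std::vector<std::pair<int,int> > pts;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (m(i, j) == 0) continue;
      bool edge = (i == 0 || i == H - 1 || j == 0 || j == W - 1);
      if (!edge)
        edge = m(i - 1, j) == 0 || m(i + 1, j) == 0 ||
               m(i, j - 1) == 0 || m(i, j + 1) == 0;
      if (edge) pts.push_back(std::make_pair(i, j));
    }
  return pts;
}

// [[Rcpp::export]]
double hausdorff_cpp(IntegerMatrix A, IntegerMatrix B,
                     double sp_row, double sp_col) {
  std::vector<std::pair<int,int> > pa = boundary_points(A);
  std::vector<std::pair<int,int> > pb = boundary_points(B);
  if (pa.empty() || pb.empty()) return NA_REAL;
  double hmax = 0.0;
  for (int pass = 0; pass < 2; ++pass) {
    const std::vector<std::pair<int,int> >& P = pass ? pb : pa;
    const std::vector<std::pair<int,int> >& Q = pass ? pa : pb;
    for (size_t u = 0; u < P.size(); ++u) {
      double dmin = R_PosInf;
      for (size_t v = 0; v < Q.size(); ++v) {
        const double dr = (P[u].first - Q[v].first) * sp_row;
        const double dc = (P[u].second - Q[v].second) * sp_col;
        const double d2 = dr * dr + dc * dc;
        if (d2 < dmin) dmin = d2;
      }
      if (dmin > hmax) hmax = dmin;
    }
  }
  return std::sqrt(hmax);
}
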