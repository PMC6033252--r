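// LOCO-I regular-mode plane codec (the JPEG-LS core): median-edge-detector
// prediction, 365 quantized-gradient contexts, bias correction, plain Rice
// error mapping M(e) = 2e / -2e-1, and limited-length Golomb-Rice coding.
// Run mode is intentionally omitted; the stream carries its own 13-byte
// header (magic "JLSR", rows u32, cols u32, bits u8, little-endian) and is
// not an ISO-14495-1 interchange bitstream.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

struct BitWriter {
  std::vector<uint8_t> buf;
  int nfree = 0; // free bits in last byte
  void put_bit(int b) {
    if (nfree == 0) {
      buf.push_back(0);
      nfree = 8;
    }
    if (b) buf.back() |= (uint8_t)(1u << (nfree - 1)); // MSB-first
    --nfree;
  }
  void put_bits(uint32_t v, int n) {
    for (int i = n - 1; i >= 0; --i) put_bit((v >> i) & 1u);
  }
};

struct BitReader {
  const uint8_t* p;
  size_t nbytes;
  size_t pos = 0; // bit position
  explicit BitReader(const uint8_t* p_, size_t n_) : p(p_), nbytes(n_) {}
  int get_bit() {
    if (pos >= nbytes * 8)
      throw std::range_error("truncated stream: bit budget exhausted");
    int b = (p[pos >> 3] >> (7 - (pos & 7))) & 1;
    ++pos;
    return b;
  }
  uint32_t get_bits(int n) {
    uint32_t v = 0;
    for (int i = 0; i < n; ++i) v = (v << 1) | (uint32_t)get_bit();
    return v;
  }
};

struct Ctx {
  std::vector<int64_t> A, B, N;
  std::vector<int> C;
  int T1, T2, T3;
  int range, maxval, qbpp, limit, cap;
  Ctx(int bits) {
    maxval = (1 << bits) - 1;
    range = maxval + 1;
    qbpp = bits;
    int bpp = bits > 8 ? bits : 8;
    limit = 2 * (bpp + (bpp > 8 ? bpp : 8));
    cap = limit - qbpp - 1;
    int factor = ((maxval < 4095 ? maxval : 4095) + 128) / 256;
    T1 = factor + 2;
    T2 = 4 * factor + 3;
    T3 = 17 * factor + 4;
    int ainit = (range + 32) / 64;
    if (ainit < 2) ainit = 2;
    A.assign(365, ainit);
    B.assign(365, 0);
    N.assign(365, 1);
    C.assign(365, 0);
  }
  int quantize(int d) const {
    if (d <= -T3) return -4;
    if (d <= -T2) return -3;
    if (d <= -T1) return -2;
    if (d < 0) return -1;
    if (d == 0) return 0;
    if (d < T1) return 1;
    if (d < T2) return 2;
    if (d < T3) return 3;
    return 4;
  }
  int golomb_k(int q) const {
    int k = 0;
    while ((N[q] << k) < A[q]) ++k;
    return k;
  }
  void update(int q, int e) {
    B[q] += e;
    A[q] += (e >= 0) ? e : -e;
    if (N[q] == 64) {
      A[q] >>= 1;
      B[q] = (B[q] >= 0) ? (B[q] >> 1) : -((1 - B[q]) >> 1);
      N[q] >>= 1;
    }
    ++N[q];
    if (B[q] <= -N[q]) {
      if (C[q] > -128) --C[q];
      B[q] += N[q];
      if (B[q] <= -N[q]) B[q] = -N[q] + 1;
    } else if (B[q] > 0) {
      if (C[q] < 127) ++C[q];
      B[q] -= N[q];
      if (B[q] > 0) B[q] = 0;
    }
  }
};

inline int med(int a, int b, int c) {
  int mn = a < b ? a : b, mx = a < b ? b : a;
  if (c >= mx) return mn;
  if (c <= mn) return mx;
  return a + b - c;
}

// neighbors of sample (i,j) in the causal template; out-of-frame rules:
// row 0 -> b = c = d = 0; col 0 -> a = b, c = b; last col -> d = b.
inline void neighbors(const IntegerMatrix& x, int i, int j,
                      int& a, int& b, int& c, int& d) {
  const int nc = x.ncol();
  b = (i > 0) ? x(i - 1, j) : 0;
  c = (i > 0) ? ((j > 0) ? x(i - 1, j - 1) : b) : 0;
  d = (i > 0) ? ((j < nc - 1) ? x(i - 1, j + 1) : b) : 0;
  a = (j > 0) ? x(i, j - 1) : b;
}

const char MAGIC[4] = {'J', 'L', 'S', 'R'};

} // namespace

// [[Rcpp::export(name = ".jls_encode")]]
List jls_encode(IntegerMatrix x, int bits, bool with_state) {
  const int nr = x.nrow(), nc = x.ncol();
  Ctx ctx(bits);
  BitWriter bw;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      int a, b, c, d;
      neighbors(x, i, j, a, b, c, d);
      int q1 = ctx.quantize(d - b), q2 = ctx.quantize(b - c),
          q3 = ctx.quantize(c - a);
      int qidx = 81 * q1 + 9 * q2 + q3;
      int sign = qidx < 0 ? -1 : 1;
      int q = qidx < 0 ? -qidx : qidx;
      int px = med(a, b, c) + sign * ctx.C[q];
      if (px < 0) px = 0;
      if (px > ctx.maxval) px = ctx.maxval;
      int e = x(i, j) - px;
      if (sign < 0) e = -e;
      e = ((e % ctx.range) + ctx.range) % ctx.range;
      if (e >= ctx.range / 2) e -= ctx.range;
      int k = ctx.golomb_k(q);
      uint32_t M = (e >= 0) ? (uint32_t)(2 * e) : (uint32_t)(-2 * e - 1);
      uint32_t u = M >> k;
      if ((int)u < ctx.cap) {
        for (uint32_t t = 0; t < u; ++t) bw.put_bit(1);
        bw.put_bit(0);
        bw.put_bits(M & ((1u << k) - 1u), k);
      } else {
        for (int t = 0; t < ctx.cap; ++t) bw.put_bit(1);
        bw.put_bit(0);
        bw.put_bits(M, ctx.qbpp);
      }
      ctx.update(q, e);
    }
  }
  // header + payload
  RawVector out(13 + bw.buf.size());
  for (int t = 0; t < 4; ++t) out[t] = (Rbyte)MAGIC[t];
  uint32_t r = (uint32_t)nr, ccc = (uint32_t)nc;
  for (int t = 0; t < 4; ++t) out[4 + t] = (Rbyte)((r >> (8 * t)) & 0xFF);
  for (int t = 0; t < 4; ++t) out[8 + t] = (Rbyte)((ccc >> (8 * t)) & 0xFF);
  out[12] = (Rbyte)bits;
  std::copy(bw.buf.begin(), bw.buf.end(), out.begin() + 13);

  List res = List::create(_["stream"] = out);
  if (with_state) {
    res["A"] = NumericVector(ctx.A.begin(), ctx.A.end());
    res["B"] = NumericVector(ctx.B.begin(), ctx.B.end());
    res["C"] = IntegerVector(ctx.C.begin(), ctx.C.end());
    res["N"] = NumericVector(ctx.N.begin(), ctx.N.end());
  }
  return res;
}

// [[Rcpp::export(name = ".jls_decode")]]
List jls_decode(RawVector stream, bool with_state) {
  if (stream.size() < 13)
    stop("format error: stream shorter than header");
  for (int t = 0; t < 4; ++t)
    if ((char)stream[t] != MAGIC[t])
      stop("format error: bad magic");
  uint32_t nr = 0, nc = 0;
  for (int t = 3; t >= 0; --t) nr = (nr << 8) | (uint32_t)stream[4 + t];
  for (int t = 3; t >= 0; --t) nc = (nc << 8) | (uint32_t)stream[8 + t];
  int bits = (int)stream[12];
  if (bits < 8 || bits > 16 || nr == 0 || nc == 0)
    stop("format error: bad header fields");

  Ctx ctx(bits);
  BitReader br((const uint8_t*)RAW(stream) + 13, stream.size() - 13);
  IntegerMatrix x((int)nr, (int)nc);
  try {
    for (int i = 0; i < (int)nr; ++i) {
      for (int j = 0; j < (int)nc; ++j) {
        int a, b, c, d;
        neighbors(x, i, j, a, b, c, d);
        int q1 = ctx.quantize(d - b), q2 = ctx.quantize(b - c),
            q3 = ctx.quantize(c - a);
        int qidx = 81 * q1 + 9 * q2 + q3;
        int sign = qidx < 0 ? -1 : 1;
        int q = qidx < 0 ? -qidx : qidx;
        int px = med(a, b, c) + sign * ctx.C[q];
        if (px < 0) px = 0;
        if (px > ctx.maxval) px = ctx.maxval;
        int k = ctx.golomb_k(q);
        uint32_t u = 0;
        while (br.get_bit()) {
          ++u;
          if ((int)u > ctx.cap)
            throw std::range_error("corrupt stream: unary run exceeds cap");
        }
        uint32_t M;
        if ((int)u < ctx.cap) {
          M = (u << k) | br.get_bits(k);
        } else {
          M = br.get_bits(ctx.qbpp);
        }
        int e = (M % 2 == 0) ? (int)(M / 2) : -((int)M + 1) / 2;
        int ecoded = e;
        if (sign < 0) e = -e;
        int v = ((px + e) % ctx.range + ctx.range) % ctx.range;
        x(i, j) = v;
        ctx.update(q, ecoded);
      }
    }
  } catch (std::range_error& err) {
    stop("truncation error: %s", err.what());
  }

  List res = List::create(_["pixels"] = x, _["bits"] = bits);
  if (with_state) {
    res["A"] = NumericVector(ctx.A.begin(), ctx.A.end());
    res["B"] = NumericVector(ctx.B.begin(), ctx.B.end());
    res["C"] = IntegerVector(ctx.C.begin(), ctx.C.end());
    res["N"] = NumericVector(ctx.N.begin(), ctx.N.end());
  }
  return res;
}

// [[Rcpp::export(name = ".adler32")]]
double adler32(RawVector data) {
  uint32_t a = 1, b = 0;
  const uint32_t MOD = 65521;
  for (R_xlen_t i = 0; i < data.size(); ++i) {
    a = (a + (uint32_t)data[i]) % MOD;
    b = (b + a) % MOD;
  }
  return (double)(((uint64_t)b << 16) | a);
}
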