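#include <Rcpp.h>
#include <cstring>
#include <vector>

using namespace Rcpp;

// LZ4 block-format codec. Greedy hash-chain-free matcher (single-entry hash
// table), emitting the standard token / literal / offset / match stream.
// Framing follows the 4-byte little-endian uncompressed-size prefix used by
// the numcodecs "lz4" codec so that stored chunks are readable outside R.

static inline uint32_t read32le(const uint8_t* p) {
  uint32_t v;
  std::memcpy(&v, p, 4);
  return v;  // assumes little-endian host; checked at load time in R
}

static const int MINMATCH = 4;
static const int MFLIMIT = 12;      // last match must start >= 12 bytes from end
static const int LASTLITERALS = 5;  // last 5 bytes are always literals

static void lz4_compress_core(const uint8_t* src, int n, std::vector<uint8_t>& out) {
  int anchor = 0;
  if (n >= MFLIMIT) {
    const int mflimit = n - MFLIMIT;
    const int matchlimit = n - LASTLITERALS;
    std::vector<int> htab(1 << 16, -1);
    int ip = 0;
    while (ip <= mflimit) {
      uint32_t seq = read32le(src + ip);
      uint32_t h = (uint32_t)((seq * 2654435761u) >> 16);
      int cand = htab[h];
      htab[h] = ip;
      if (cand >= 0 && (ip - cand) <= 65535 && read32le(src + cand) == seq) {
        int mlen = MINMATCH;
        while (ip + mlen < matchlimit && src[cand + mlen] == src[ip + mlen]) mlen++;
        int litlen = ip - anchor;
        int mtok = mlen - MINMATCH;
        uint8_t token = (uint8_t)(((litlen < 15 ? litlen : 15) << 4) |
                                  (mtok < 15 ? mtok : 15));
        out.push_back(token);
        if (litlen >= 15) {
          int r = litlen - 15;
          while (r >= 255) { out.push_back(255); r -= 255; }
          out.push_back((uint8_t)r);
        }
        out.insert(out.end(), src + anchor, src + ip);
        int offset = ip - cand;
        out.push_back((uint8_t)(offset & 0xff));
        out.push_back((uint8_t)(offset >> 8));
        if (mtok >= 15) {
          int r = mtok - 15;
          while (r >= 255) { out.push_back(255); r -= 255; }
          out.push_back((uint8_t)r);
        }
        ip += mlen;
        anchor = ip;
      } else {
        ip++;
      }
    }
  }
  // terminal literal run
  int litlen = n - anchor;
  out.push_back((uint8_t)((litlen < 15 ? litlen : 15) << 4));
  if (litlen >= 15) {
    int r = litlen - 15;
    while (r >= 255) { out.push_back(255); r -= 255; }
    out.push_back((uint8_t)r);
  }
  out.insert(out.end(), src + anchor, src + n);
}

// [[Rcpp::export]]
RawVector lz4_compress_raw(RawVector input) {
  const int n = input.size();
  const uint8_t* src = (const uint8_t*)RAW(input);
  std::vector<uint8_t> out;
  out.reserve((size_t)n + n / 128 + 16);
  // 4-byte little-endian original size prefix
  out.push_back((uint8_t)(n & 0xff));
  out.push_back((uint8_t)((n >> 8) & 0xff));
  out.push_back((uint8_t)((n >> 16) & 0xff));
  out.push_back((uint8_t)((n >> 24) & 0xff));
  lz4_compress_core(src, n, out);
  RawVector res(out.size());
  std::memcpy(RAW(res), out.data(), out.size());
  return res;
}

// [[Rcpp::export]]
RawVector lz4_decompress_raw(RawVector input) {
  const int n = input.size();
  if (n < 5) stop("corrupt LZ4 stream: too short");
  const uint8_t* src = (const uint8_t*)RAW(input);
  uint32_t dlen = read32le(src);
  RawVector res((int)dlen);
  uint8_t* dst = (uint8_t*)RAW(res);
  int ip = 4, op = 0;
  const int dn = (int)dlen;
  while (ip < n) {
    uint8_t token = src[ip++];
    int litlen = token >> 4;
    if (litlen == 15) {
      uint8_t b;
      do {
        if (ip >= n) stop("corrupt LZ4 stream: truncated literal length");
        b = src[ip++];
        litlen += b;
      } while (b == 255);
    }
    if (ip + litlen > n || op + litlen > dn) stop("corrupt LZ4 stream: literal overrun");
    std::memcpy(dst + op, src + ip, litlen);
    ip += litlen;
    op += litlen;
    if (ip >= n) break;  // terminal sequence has no match part
    if (ip + 2 > n) stop("corrupt LZ4 stream: truncated offset");
    int offset = src[ip] | (src[ip + 1] << 8);
    ip += 2;
    if (offset == 0 || offset > op) stop("corrupt LZ4 stream: bad offset");
    int mlen = (token & 0x0f) + MINMATCH;
    if ((token & 0x0f) == 15) {
      uint8_t b;
      do {
        if (ip >= n) stop("corrupt LZ4 stream: truncated match length");
        b = src[ip++];
        mlen += b;
      } while (b == 255);
    }
    if (op + mlen > dn) stop("corrupt LZ4 stream: match overrun");
    for (int i = 0; i < mlen; i++) {  // byte-wise: overlapping copies are valid
      dst[op] = dst[op - offset];
      op++;
    }
  }
  if (op != dn) stop("corrupt LZ4 stream: size mismatch");
  return res;
}

// Byte-shuffle filter: regroup the k-th byte of every element together,
// improving compressibility of fixed-width numeric data.
// out[j*nelem + i] = in[i*elemsize + j]

// [[Rcpp::export]]
RawVector byte_shuffle(RawVector input, int elemsize) {
  const R_xlen_t n = input.size();
  if (elemsize <= 1) return input;
  if (n % elemsize != 0) stop("input length not divisible by element size");
  const R_xlen_t nelem = n / elemsize;
  RawVector out(n);
  const uint8_t* in = (const uint8_t*)RAW(input);
  uint8_t* o = (uint8_t*)RAW(out);
  for (int j = 0; j < elemsize; j++) {
    const uint8_t* ip = in + j;
    uint8_t* op = o + (R_xlen_t)j * nelem;
    for (R_xlen_t i = 0; i < nelem; i++) op[i] = ip[i * elemsize];
  }
  return out;
}

// [[Rcpp::export]]
RawVector byte_unshuffle(RawVector input, int elemsize) {
  const R_xlen_t n = input.size();
  if (elemsize <= 1) return input;
  if (n % elemsize != 0) stop("input length not divisible by element size");
  const R_xlen_t nelem = n / elemsize;
  RawVector out(n);
  const uint8_t* in = (const uint8_t*)RAW(input);
  uint8_t* o = (uint8_t*)RAW(out);
  for (int j = 0; j < elemsize; j++) {
    const uint8_t* ip = in + (R_xlen_t)j * nelem;
    uint8_t* op = o + j;
    for (R_xlen_t i = 0; i < nelem; i++) op[i * elemsize] = ip[i];
  }
  return out;
}
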