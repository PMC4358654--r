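// Bit-level codec for the U3D byte stream.
//
// Two channels share one bit stream:
//   * raw channel: fixed-width little-endian values, bits packed LSB-first
//     into bytes (an aligned u32 therefore appears as 4 little-endian bytes);
//   * compressed channel: a 16-bit context-adaptive arithmetic coder.
//     Dynamic contexts (1 .. 0x3FF) keep an adaptive symbol histogram with an
//     escape symbol (0); a value never seen in its context escapes to a raw
//     32-bit write and is then added to the histogram. Static contexts
//     (0x400 + n) code a value in [0, n) with a uniform model and no state.
//
// Switching from the compressed to the raw channel flushes the coder state
// (two or more disambiguating bits); the reader performs the mirror resync,
// so read(write(x)) = x holds for any interleaving, provided reader and
// writer issue the same call sequence with the same contexts.

#include <Rcpp.h>
#include <cstring>
#include <map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const uint32_t AC_STATIC_FULL  = 0x00000400; // first static context
static const uint32_t AC_MAX_RANGE    = AC_STATIC_FULL + 0x00003FFF;
static const uint32_t AC_MAX_CUM_FREQ = 0x00001FFF;  // histogram rescale limit
static const uint32_t AC_MAX_SYMBOL   = 0x0000FFFF;  // larger values always escape
static const uint32_t AC_HALF    = 0x8000;
static const uint32_t AC_QUARTER = 0x4000;

struct Histogram {
  std::map<uint32_t, uint32_t> counts; // symbols >= 1 only
  uint32_t escape = 1;                 // count of the escape symbol (0)
  uint32_t total = 1;

  uint32_t freq(uint32_t sym) const {
    if (sym == 0) return escape;
    std::map<uint32_t, uint32_t>::const_iterator it = counts.find(sym);
    return it == counts.end() ? 0u : it->second;
  }
  // cumulative frequency of all symbols ordered escape-first then ascending
  uint32_t cum(uint32_t sym) const {
    if (sym == 0) return 0;
    uint32_t c = escape;
    for (std::map<uint32_t, uint32_t>::const_iterator it = counts.begin();
         it != counts.end() && it->first < sym; ++it)
      c += it->second;
    return c;
  }
  void add(uint32_t sym) {
    if (sym > AC_MAX_SYMBOL) return;
    if (total >= AC_MAX_CUM_FREQ) { // rescale, keep escape >= 1
      uint32_t t = 0;
      for (std::map<uint32_t, uint32_t>::iterator it = counts.begin();
           it != counts.end();) {
        it->second >>= 1;
        if (it->second == 0) counts.erase(it++);
        else { t += it->second; ++it; }
      }
      escape >>= 1; if (escape == 0) escape = 1;
      total = t + escape;
    }
    counts[sym] += 1;
    total += 1;
  }
  // symbol whose interval contains target; fills cum/freq of that symbol
  uint32_t find(uint32_t target, uint32_t &cumOut, uint32_t &freqOut) const {
    if (target < escape) { cumOut = 0; freqOut = escape; return 0; }
    uint32_t c = escape;
    for (std::map<uint32_t, uint32_t>::const_iterator it = counts.begin();
         it != counts.end(); ++it) {
      if (target < c + it->second) { cumOut = c; freqOut = it->second; return it->first; }
      c += it->second;
    }
    stop("u3d codec: context desynchronization (cumulative target %d >= total %d)",
         (int)target, (int)total);
    return 0; // unreached
  }
};

// ---------------------------------------------------------------- writer ---

struct BitWriter {
  std::vector<uint8_t> bytes;
  uint32_t bit_in_last = 0;            // 0..7; 0 means byte-aligned
  uint32_t low = 0, high = 0xFFFF, underflow = 0;
  bool ac_active = false;
  std::map<uint32_t, Histogram> ctx;

  void put_bit(uint32_t b) {
    if (bit_in_last == 0) bytes.push_back(0);
    if (b) bytes.back() |= (uint8_t)(1u << bit_in_last);
    bit_in_last = (bit_in_last + 1) & 7;
  }
  void put_bits(uint64_t v, int n) {
    for (int i = 0; i < n; ++i) put_bit((uint32_t)((v >> i) & 1));
  }
  // terminate the pending arithmetic interval so any following bits decode
  // inside it; resets the coder state
  void flush_ac() {
    if (!ac_active) return;
    underflow++;
    uint32_t b = (low >> 14) & 1;
    put_bit(b);
    for (; underflow > 0; underflow--) put_bit(1 - b);
    low = 0; high = 0xFFFF; underflow = 0; ac_active = false;
  }
  void encode(uint32_t cum, uint32_t cnt, uint32_t tot) {
    uint32_t range = high - low + 1;
    high = low + (uint32_t)(((uint64_t)range * (cum + cnt)) / tot) - 1;
    low  = low + (uint32_t)(((uint64_t)range * cum) / tot);
    for (;;) {
      if ((low & AC_HALF) == (high & AC_HALF)) {
        uint32_t b = (low >> 15) & 1;
        put_bit(b);
        for (; underflow > 0; underflow--) put_bit(1 - b);
      } else if ((low & AC_QUARTER) && !(high & AC_QUARTER)) {
        underflow++;
        low -= AC_QUARTER; high -= AC_QUARTER;
      } else break;
      low  = (low << 1) & 0xFFFF;
      high = ((high << 1) | 1) & 0xFFFF;
    }
    ac_active = true;
  }
  void write_compressed(uint32_t context, uint32_t value) {
    if (context == 0 || context > AC_MAX_RANGE)
      stop("u3d codec: invalid compression context %d", (int)context);
    if (context >= AC_STATIC_FULL) {
      uint32_t rng = context - AC_STATIC_FULL;
      if (rng == 0 || value >= rng)
        stop("u3d codec: value %d out of range for static context of size %d",
             (int)value, (int)rng);
      encode(value, 1, rng);
      return;
    }
    Histogram &h = ctx[context];
    uint32_t sym = value + 1;
    uint32_t f = (sym <= AC_MAX_SYMBOL) ? h.freq(sym) : 0;
    if (f == 0) {                      // escape: raw 32-bit value follows
      encode(0, h.escape, h.total);
      flush_ac();
      put_bits(value, 32);
      h.add(sym);
    } else {
      encode(h.cum(sym), f, h.total);
      h.add(sym);
    }
  }
  void write_raw(uint64_t v, int nbits) { flush_ac(); put_bits(v, nbits); }
  void align4() {
    flush_ac();
    bit_in_last = 0; // residual bits of the last byte are already zero
    while (bytes.size() % 4) bytes.push_back(0);
  }
};

// ---------------------------------------------------------------- reader ---

struct BitReader {
  std::vector<uint8_t> bytes;
  uint64_t bitpos = 0;                 // bits consumed by the raw channel /
                                       // shifted out of the code register
  uint32_t low = 0, high = 0xFFFF, code = 0;
  bool ac_active = false;
  std::map<uint32_t, Histogram> ctx;

  uint64_t bit_length() const { return (uint64_t)bytes.size() * 8; }
  uint32_t get_bit(uint64_t p) const { // zero-padded peek past the end
    uint64_t byte = p >> 3;
    if (byte >= bytes.size()) return 0;
    return (bytes[byte] >> (p & 7)) & 1;
  }
  uint64_t read_bits(int n) {
    if (bitpos + (uint64_t)n > bit_length())
      stop("u3d codec: read past end of stream (bit %d of %d)",
           (int)(bitpos + n), (int)bit_length());
    uint64_t v = 0;
    for (int i = 0; i < n; ++i) v |= (uint64_t)get_bit(bitpos + i) << i;
    bitpos += n;
    return v;
  }
  void ensure_ac() { // load the 16-bit lookahead window, MSB-first
    if (ac_active) return;
    low = 0; high = 0xFFFF; code = 0;
    for (int i = 0; i < 16; ++i) code = (code << 1) | get_bit(bitpos + i);
    ac_active = true;
  }
  // writer flushed with underflow+2 bits, of which `underflow` were already
  // consumed into the code register by the underflow branches below
  void flush_sync() {
    if (!ac_active) return;
    bitpos += 2;
    ac_active = false;
  }
  // mirror of BitWriter::encode, carrying the code register along
  void decode_update(uint32_t cum, uint32_t cnt, uint32_t tot) {
    uint32_t range = high - low + 1;
    high = low + (uint32_t)(((uint64_t)range * (cum + cnt)) / tot) - 1;
    low  = low + (uint32_t)(((uint64_t)range * cum) / tot);
    for (;;) {
      if ((low & AC_HALF) == (high & AC_HALF)) {
        // masking below drops the shared MSB from all three registers
      } else if ((low & AC_QUARTER) && !(high & AC_QUARTER)) {
        code -= AC_QUARTER; low -= AC_QUARTER; high -= AC_QUARTER;
      } else break;
      low  = (low << 1) & 0xFFFF;
      high = ((high << 1) | 1) & 0xFFFF;
      code = ((code << 1) | get_bit(bitpos + 16)) & 0xFFFF;
      bitpos++;
    }
  }
  uint32_t read_compressed(uint32_t context) {
    if (context == 0 || context > AC_MAX_RANGE)
      stop("u3d codec: invalid compression context %d", (int)context);
    ensure_ac();
    uint32_t range = high - low + 1;
    if (context >= AC_STATIC_FULL) {
      uint32_t rng = context - AC_STATIC_FULL;
      if (rng == 0) stop("u3d codec: empty static context");
      uint32_t target = (uint32_t)((((uint64_t)(code - low) + 1) * rng - 1) / range);
      if (target >= rng) target = rng - 1; // corrupted stream guard
      decode_update(target, 1, rng);
      return target;
    }
    Histogram &h = ctx[context];
    uint32_t target = (uint32_t)((((uint64_t)(code - low) + 1) * h.total - 1) / range);
    if (target >= h.total) target = h.total - 1; // corrupted stream guard
    uint32_t cum = 0, cnt = 0;
    uint32_t sym = h.find(target, cum, cnt);
    decode_update(cum, cnt, h.total);
    uint32_t value;
    if (sym == 0) {                    // escape: raw 32-bit value follows
      flush_sync();
      value = (uint32_t)read_bits(32);
      h.add(value + 1);
    } else {
      value = sym - 1;
      h.add(sym);
    }
    return value;
  }
  uint64_t read_raw(int nbits) { flush_sync(); return read_bits(nbits); }
  void align4() {
    flush_sync();
    if (bitpos % 8) bitpos += 8 - bitpos % 8;
    uint64_t byte = bitpos >> 3;
    bitpos += ((4 - byte % 4) % 4) * 8;
  }
};

// ------------------------------------------------------------ R bindings ---

static BitWriter* bw(SEXP p) {
  XPtr<BitWriter> x(p);
  if (!x) stop("invalid bit writer handle");
  return x.get();
}
static BitReader* br(SEXP p) {
  XPtr<BitReader> x(p);
  if (!x) stop("invalid bit reader handle");
  return x.get();
}
static uint64_t chk_val(double v, double maxv, const char* what) {
  if (ISNAN(v) || v < 0 || v > maxv || v != std::floor(v))
    stop("u3d codec: %s out of range or not a whole number (%f)", what, v);
  return (uint64_t)v;
}

// [[Rcpp::export]]
SEXP cpp_bw_new() { return XPtr<BitWriter>(new BitWriter(), true); }

// [[Rcpp::export]]
void cpp_bw_u8(SEXP p, NumericVector v) {
  BitWriter* w = bw(p);
  for (double x : v) w->write_raw(chk_val(x, 255.0, "u8"), 8);
}
// [[Rcpp::export]]
void cpp_bw_u16(SEXP p, NumericVector v) {
  BitWriter* w = bw(p);
  for (double x : v) w->write_raw(chk_val(x, 65535.0, "u16"), 16);
}
// [[Rcpp::export]]
void cpp_bw_u32(SEXP p, NumericVector v) {
  BitWriter* w = bw(p);
  for (double x : v) w->write_raw(chk_val(x, 4294967295.0, "u32"), 32);
}
// [[Rcpp::export]]
void cpp_bw_u64(SEXP p, NumericVector v) {
  BitWriter* w = bw(p);
  // R doubles hold integers exactly up to 2^53; ample for file sizes
  for (double x : v) w->write_raw(chk_val(x, 9007199254740992.0, "u64"), 64);
}
// [[Rcpp::export]]
void cpp_bw_f32(SEXP p, NumericVector v) {
  BitWriter* w = bw(p);
  for (double x : v) {
    float f = (float)x;
    uint32_t u; std::memcpy(&u, &f, 4);
    w->write_raw(u, 32);
  }
}
// [[Rcpp::export]]
void cpp_bw_f64(SEXP p, NumericVector v) {
  BitWriter* w = bw(p);
  for (double x : v) {
    uint64_t u; std::memcpy(&u, &x, 8);
    w->write_raw(u, 64);
  }
}
// [[Rcpp::export]]
void cpp_bw_string(SEXP p, std::string s) {
  BitWriter* w = bw(p);
  if (s.size() > 65535) stop("u3d codec: string longer than 65535 bytes");
  w->write_raw((uint64_t)s.size(), 16);
  for (size_t i = 0; i < s.size(); ++i) w->put_bits((uint8_t)s[i], 8);
}
// [[Rcpp::export]]
void cpp_bw_compressed(SEXP p, double context, NumericVector v) {
  BitWriter* w = bw(p);
  uint32_t c = (uint32_t)chk_val(context, 4294967295.0, "context");
  for (double x : v) w->write_compressed(c, (uint32_t)chk_val(x, 4294967295.0, "value"));
}
// [[Rcpp::export]]
void cpp_bw_raw(SEXP p, RawVector r) {
  BitWriter* w = bw(p);
  w->flush_ac();
  if (w->bit_in_last != 0) stop("u3d codec: raw append requires byte alignment");
  w->bytes.insert(w->bytes.end(), r.begin(), r.end());
}
// [[Rcpp::export]]
void cpp_bw_align4(SEXP p) { bw(p)->align4(); }
// [[Rcpp::export]]
RawVector cpp_bw_bytes(SEXP p) {
  BitWriter* w = bw(p);
  w->flush_ac();
  w->bit_in_last = 0;
  return RawVector(w->bytes.begin(), w->bytes.end());
}
// [[Rcpp::export]]
double cpp_bw_size(SEXP p) { return (double)bw(p)->bytes.size(); }

// [[Rcpp::export]]
SEXP cpp_br_new(RawVector r) {
  BitReader* rd = new BitReader();
  rd->bytes.assign(r.begin(), r.end());
  return XPtr<BitReader>(rd, true);
}
// [[Rcpp::export]]
NumericVector cpp_br_u8(SEXP p, int n) {
  BitReader* r = br(p); NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (double)r->read_raw(8);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_br_u16(SEXP p, int n) {
  BitReader* r = br(p); NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (double)r->read_raw(16);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_br_u32(SEXP p, int n) {
  BitReader* r = br(p); NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (double)r->read_raw(32);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_br_u64(SEXP p, int n) {
  BitReader* r = br(p); NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (double)r->read_raw(64);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_br_f32(SEXP p, int n) {
  BitReader* r = br(p); NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    uint32_t u = (uint32_t)r->read_raw(32);
    float f; std::memcpy(&f, &u, 4);
    out[i] = (double)f;
  }
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_br_f64(SEXP p, int n) {
  BitReader* r = br(p); NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    uint64_t u = r->read_raw(64);
    double d; std::memcpy(&d, &u, 8);
    out[i] = d;
  }
  return out;
}
// [[Rcpp::export]]
std::string cpp_br_string(SEXP p) {
  BitReader* r = br(p);
  uint32_t n = (uint32_t)r->read_raw(16);
  std::string s(n, '\0');
  for (uint32_t i = 0; i < n; ++i) s[i] = (char)r->read_bits(8);
  return s;
}
// [[Rcpp::export]]
NumericVector cpp_br_compressed(SEXP p, double context, int n) {
  BitReader* r = br(p); NumericVector out(n);
  uint32_t c = (uint32_t)chk_val(context, 4294967295.0, "context");
  for (int i = 0; i < n; ++i) out[i] = (double)r->read_compressed(c);
  return out;
}
// [[Rcpp::export]]
void cpp_br_align4(SEXP p) { br(p)->align4(); }
// [[Rcpp::export]]
double cpp_br_pos(SEXP p) { // byte position (rounded up)
  BitReader* r = br(p);
  return (double)((r->bitpos + 7) >> 3);
}
// [[Rcpp::export]]
double cpp_br_remaining_bits(SEXP p) {
  BitReader* r = br(p);
  uint64_t len = r->bit_length();
  return (double)(len > r->bitpos ? len - r->bitpos : 0);
}
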