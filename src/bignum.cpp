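// Exact integer arithmetic for the null distribution of Friedman rank-sum
// differences.  Counts grow like {k(k-1)}^n, far beyond 2^53, so all
// combinatorial work is done on arbitrary-precision integers (little-endian
// base-2^32 limbs) and only converted to double at the reporting boundary.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <string>
#include <vector>

using Rcpp::CharacterVector;
using Rcpp::IntegerVector;
using Rcpp::List;
using Rcpp::stop;

typedef std::vector<uint32_t> Mag;

static void trim(Mag &a) {
  while (!a.empty() && a.back() == 0u) a.pop_back();
}

static int cmpmag(const Mag &a, const Mag &b) {
  if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
  for (size_t i = a.size(); i-- > 0;)
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  return 0;
}

static Mag addmag(const Mag &a, const Mag &b) {
  const Mag &x = a.size() >= b.size() ? a : b;
  const Mag &y = a.size() >= b.size() ? b : a;
  Mag r(x.size() + 1, 0u);
  uint64_t carry = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    uint64_t s = carry + x[i] + (i < y.size() ? y[i] : 0u);
    r[i] = (uint32_t)s;
    carry = s >> 32;
  }
  r[x.size()] = (uint32_t)carry;
  trim(r);
  return r;
}

// requires a >= b
static Mag submag(const Mag &a, const Mag &b) {
  Mag r(a.size(), 0u);
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t s = (int64_t)a[i] - borrow - (i < b.size() ? (int64_t)b[i] : 0);
    if (s < 0) { s += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
    r[i] = (uint32_t)s;
  }
  trim(r);
  return r;
}

static Mag mulsmall(const Mag &a, uint32_t m) {
  if (m == 0u || a.empty()) return Mag();
  Mag r(a.size() + 1, 0u);
  uint64_t carry = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t s = (uint64_t)a[i] * m + carry;
    r[i] = (uint32_t)s;
    carry = s >> 32;
  }
  r[a.size()] = (uint32_t)carry;
  trim(r);
  return r;
}

static Mag mulmag(const Mag &a, const Mag &b) {
  if (a.empty() || b.empty()) return Mag();
  Mag r(a.size() + b.size(), 0u);
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t carry = 0;
    uint64_t ai = a[i];
    for (size_t j = 0; j < b.size(); ++j) {
      uint64_t s = r[i + j] + ai * b[j] + carry;
      r[i + j] = (uint32_t)s;
      carry = s >> 32;
    }
    size_t pos = i + b.size();
    while (carry) {
      uint64_t s = (uint64_t)r[pos] + carry;
      r[pos] = (uint32_t)s;
      carry = s >> 32;
      ++pos;
    }
  }
  trim(r);
  return r;
}

// in-place divide by small, returns remainder
static uint32_t divsmall(Mag &a, uint32_t d) {
  uint64_t rem = 0;
  for (size_t i = a.size(); i-- > 0;) {
    uint64_t cur = (rem << 32) | a[i];
    a[i] = (uint32_t)(cur / d);
    rem = cur % d;
  }
  trim(a);
  return (uint32_t)rem;
}

struct Big {
  int sign;  // -1, 0, 1
  Mag mag;
  Big() : sign(0) {}
  explicit Big(int64_t v) : sign(0) {
    uint64_t u = v < 0 ? (uint64_t)(-v) : (uint64_t)v;
    if (v != 0) sign = v < 0 ? -1 : 1;
    while (u) { mag.push_back((uint32_t)u); u >>= 32; }
  }
  bool zero() const { return sign == 0; }
};

static Big make(int sign, Mag m) {
  Big r;
  trim(m);
  if (m.empty()) return r;
  r.sign = sign;
  r.mag = std::move(m);
  return r;
}

static Big addbig(const Big &a, const Big &b) {
  if (a.zero()) return b;
  if (b.zero()) return a;
  if (a.sign == b.sign) return make(a.sign, addmag(a.mag, b.mag));
  int c = cmpmag(a.mag, b.mag);
  if (c == 0) return Big();
  if (c > 0) return make(a.sign, submag(a.mag, b.mag));
  return make(b.sign, submag(b.mag, a.mag));
}

static Big negbig(const Big &a) {
  Big r = a;
  r.sign = -r.sign;
  return r;
}

static Big mulbig(const Big &a, const Big &b) {
  if (a.zero() || b.zero()) return Big();
  return make(a.sign * b.sign, mulmag(a.mag, b.mag));
}

static Big mulbig_small(const Big &a, uint32_t m) {
  if (a.zero() || m == 0u) return Big();
  return make(a.sign, mulsmall(a.mag, m));
}

static std::string to_string(const Big &a) {
  if (a.zero()) return "0";
  Mag t = a.mag;
  std::string digits;
  while (!t.empty()) {
    uint32_t r = divsmall(t, 1000000000u);
    char buf[16];
    if (t.empty()) snprintf(buf, sizeof(buf), "%u", r);
    else snprintf(buf, sizeof(buf), "%09u", r);
    std::string chunk(buf);
    digits = chunk + digits;
  }
  return (a.sign < 0 ? "-" : "") + digits;
}

static Big from_string(const std::string &s) {
  Big r;
  size_t i = 0;
  int sign = 1;
  if (i < s.size() && (s[i] == '-' || s[i] == '+')) {
    if (s[i] == '-') sign = -1;
    ++i;
  }
  if (i >= s.size()) stop("empty big integer string");
  Mag m;
  for (; i < s.size(); ++i) {
    if (s[i] < '0' || s[i] > '9') stop("invalid big integer string '%s'", s.c_str());
    m = mulsmall(m, 10u);
    uint32_t dgt = (uint32_t)(s[i] - '0');
    if (dgt) {
      Mag one(1, dgt);
      m = addmag(m, one);
    }
  }
  return make(sign, m);
}

// binomial coefficient C(a, b) for 0 <= b <= a (falling-factorial product,
// incremental exact division keeps intermediates integral)
static Big binom_big(int64_t a, int64_t b) {
  if (b < 0 || a < b) stop("binom_big requires 0 <= b <= a");
  if (b > a - b) b = a - b;
  Big acc((int64_t)1);
  for (int64_t r = 1; r <= b; ++r) {
    int64_t f = a - b + r;
    if (f > 4294967295LL) stop("binomial factor exceeds 32-bit limb");
    acc = mulbig_small(acc, (uint32_t)f);
    Mag t = acc.mag;
    uint32_t rem = divsmall(t, (uint32_t)r);
    if (rem != 0u) stop("internal error: non-exact division in binomial");
    acc.mag = t;
    if (acc.mag.empty()) acc.sign = 0;
  }
  return acc;
}

static Big pow_small(uint64_t base, int e) {
  if (base > 4294967295ULL) stop("power base exceeds 32-bit limb");
  Big acc((int64_t)1);
  for (int i = 0; i < e; ++i) acc = mulbig_small(acc, (uint32_t)base);
  return acc;
}

static void check_kn(int k, int n) {
  if (k < 2) stop("k must be at least 2 (got %d)", k);
  if (n < 1) stop("n must be at least 1 (got %d)", n);
}

// Tail count over the signed support, W(D >= d), for nonnegative d.
// Single-sum (Vandermonde-reduced) form:
//   W(D>=d) = (-1)^n sum_h C(n,h) k^(n-h) sum_s (-1)^s C(2h,h+s) C(ks-d+h, ks-d-h)
// with the convention C(a,b)=0 for b<0 or a<b, C(a,0)=1.
static Big tail_core(int64_t d, int k, int n) {
  if (d < 0) stop("tail_core requires d >= 0");
  int64_t dmax = (int64_t)n * (k - 1);
  if (d > dmax) return Big();
  Big total;
  for (int h = 0; h <= n; ++h) {
    Big inner;
    for (int s = 0; s <= h; ++s) {
      int64_t lo = (int64_t)k * s - d - h;
      if (lo < 0) continue;
      Big t = mulbig(binom_big(lo + 2 * h, 2 * h), binom_big(2 * h, h + s));
      inner = addbig(inner, (s % 2) ? negbig(t) : t);
    }
    if (inner.zero()) continue;
    Big term = mulbig(mulbig(binom_big(n, h), pow_small((uint64_t)k, n - h)), inner);
    total = addbig(total, term);
  }
  if (n % 2) total = negbig(total);
  return total;
}

// Same tail count via the unreduced double inner sum (the "triple summation"
// expression); retained as an independent agreement check.
static Big tail_core_double(int64_t d, int k, int n) {
  if (d < 0) stop("tail_core_double requires d >= 0");
  int64_t dmax = (int64_t)n * (k - 1);
  if (d > dmax) return Big();
  Big total;
  for (int h = 0; h <= n; ++h) {
    Big inner;
    for (int i = 0; i <= h; ++i) {
      for (int j = 0; j <= h; ++j) {
        int64_t t = (int64_t)j - i;
        int64_t lo = (int64_t)k * t - d - h;
        if (lo < 0) continue;
        Big term = mulbig(mulbig(binom_big(h, i), binom_big(h, j)),
                          binom_big(lo + 2 * h, 2 * h));
        int par = (int)(((t % 2) + 2) % 2);
        inner = addbig(inner, par ? negbig(term) : term);
      }
    }
    if (inner.zero()) continue;
    Big term = mulbig(mulbig(binom_big(n, h), pow_small((uint64_t)k, n - h)), inner);
    total = addbig(total, term);
  }
  if (n % 2) total = negbig(total);
  return total;
}

// Point count W(D = d) via the generating-function composition formula; the
// h = 0 term is the empty-product case C(-1, 0) = 1, nonzero only at d = 0.
static Big point_core(int64_t d, int k, int n) {
  if (d < 0) d = -d;
  int64_t dmax = (int64_t)n * (k - 1);
  if (d > dmax) return Big();
  Big total = (d == 0) ? pow_small((uint64_t)k, n) : Big();  // h = 0 term
  for (int h = 1; h <= n; ++h) {
    Big inner;
    for (int s = 0; s <= h; ++s) {
      int64_t lo = (int64_t)k * s - d - h;
      if (lo < 0) continue;
      Big t = mulbig(binom_big(lo + 2 * h - 1, 2 * h - 1), binom_big(2 * h, h + s));
      inner = addbig(inner, (s % 2) ? negbig(t) : t);
    }
    if (inner.zero()) continue;
    Big term = mulbig(mulbig(binom_big(n, h), pow_small((uint64_t)k, n - h)), inner);
    total = addbig(total, term);
  }
  if (n % 2) total = negbig(total);
  return total;
}

// Signed tail: W(D >= d) for any integer d, using symmetry
// W(D >= -a) = total - W(D >= a + 1).
static Big tail_signed(int64_t d, int k, int n) {
  if (d >= 0) return tail_core(d, k, n);
  Big total = pow_small((uint64_t)k * (uint64_t)(k - 1), n);
  Big upper = tail_core(-d + 1, k, n);
  return addbig(total, negbig(upper));
}

// [[Rcpp::export]]
std::string cpp_tail_count(double d, int k, int n) {
  check_kn(k, n);
  return to_string(tail_signed((int64_t)d, k, n));
}

// [[Rcpp::export]]
std::string cpp_tail_count_triple(double d, int k, int n) {
  check_kn(k, n);
  if (d < 0) stop("triple-sum tail requires d >= 0");
  return to_string(tail_core_double((int64_t)d, k, n));
}

// [[Rcpp::export]]
std::string cpp_point_count(double d, int k, int n) {
  check_kn(k, n);
  return to_string(point_core((int64_t)d, k, n));
}

// Signed pmf counts by n-fold integer convolution of the per-block difference
// multiplicity vector (k - |t| copies of t for 1 <= |t| <= k-1, none at 0).
// Independent of the generating-function formulas above; used as the oracle.
static std::vector<Big> conv_counts(int k, int n) {
  int m = 2 * (k - 1) + 1;
  std::vector<uint32_t> base(m, 0u);
  for (int t = -(k - 1); t <= k - 1; ++t)
    if (t != 0) base[t + k - 1] = (uint32_t)(k - std::abs(t));
  std::vector<Big> cur(1, Big((int64_t)1));
  for (int b = 0; b < n; ++b) {
    std::vector<Big> nxt(cur.size() + m - 1);
    for (size_t i = 0; i < cur.size(); ++i) {
      if (cur[i].zero()) continue;
      for (int j = 0; j < m; ++j) {
        if (!base[j]) continue;
        nxt[i + j] = addbig(nxt[i + j], mulbig_small(cur[i], base[j]));
      }
    }
    cur = std::move(nxt);
  }
  return cur;
}

// [[Rcpp::export]]
CharacterVector cpp_conv_counts(int k, int n) {
  check_kn(k, n);
  std::vector<Big> c = conv_counts(k, n);
  CharacterVector out(c.size());
  for (size_t i = 0; i < c.size(); ++i) out[i] = to_string(c[i]);
  return out;
}

// Joint signed tail count for an incomplete design made of independent
// complete parts (k_t, n_t): convolve the per-part signed count vectors and
// sum the joint counts at and above d.  Returns numerator and denominator
// of the signed tail probability as exact integers.
// [[Rcpp::export]]
List cpp_parts_tail(double d, IntegerVector ks, IntegerVector ns) {
  int np = ks.size();
  if (np < 1 || ns.size() != np) stop("parts specification is empty or ragged");
  int64_t off = 0;
  for (int t = 0; t < np; ++t) {
    check_kn(ks[t], ns[t]);
    off += (int64_t)ns[t] * (ks[t] - 1);
  }
  std::vector<Big> joint(1, Big((int64_t)1));
  for (int t = 0; t < np; ++t) {
    std::vector<Big> part = conv_counts(ks[t], ns[t]);
    std::vector<Big> nxt(joint.size() + part.size() - 1);
    for (size_t i = 0; i < joint.size(); ++i) {
      if (joint[i].zero()) continue;
      for (size_t j = 0; j < part.size(); ++j) {
        if (part[j].zero()) continue;
        nxt[i + j] = addbig(nxt[i + j], mulbig(joint[i], part[j]));
      }
    }
    joint = std::move(nxt);
  }
  int64_t dd = (int64_t)d;
  Big num;
  int64_t start = dd + off;  // index of d in the signed support
  if (start < 0) start = 0;
  for (size_t i = (size_t)start; i < joint.size(); ++i) num = addbig(num, joint[i]);
  Big den((int64_t)1);
  for (int t = 0; t < np; ++t)
    den = mulbig(den, pow_small((uint64_t)ks[t] * (uint64_t)(ks[t] - 1), ns[t]));
  return List::create(Rcpp::Named("num") = to_string(num),
                      Rcpp::Named("den") = to_string(den));
}

// ---- generic big-integer helpers exposed to R ------------------------------

// [[Rcpp::export]]
std::string cpp_big_add(std::string a, std::string b) {
  return to_string(addbig(from_string(a), from_string(b)));
}

// [[Rcpp::export]]
std::string cpp_big_sub(std::string a, std::string b) {
  return to_string(addbig(from_string(a), negbig(from_string(b))));
}

// [[Rcpp::export]]
std::string cpp_big_mul(std::string a, std::string b) {
  return to_string(mulbig(from_string(a), from_string(b)));
}

// [[Rcpp::export]]
int cpp_big_cmp(std::string a, std::string b) {
  Big diff = addbig(from_string(a), negbig(from_string(b)));
  return diff.sign;
}

// [[Rcpp::export]]
std::string cpp_big_pow(double base, int e) {
  if (base < 0 || e < 0) stop("cpp_big_pow requires nonnegative base and exponent");
  return to_string(pow_small((uint64_t)base, e));
}

// num/den as a double; both read through their leading 96 bits in extended
// precision, so the quotient is accurate to well below display precision.
// [[Rcpp::export]]
double cpp_big_ratio(std::string num, std::string den) {
  Big a = from_string(num), b = from_string(den);
  if (b.zero()) stop("zero denominator");
  if (a.zero()) return 0.0;
  auto lead = [](const Mag &m, long &ex) {
    long double v = 0.0L;
    size_t len = m.size();
    size_t take = len < 3 ? len : 3;
    for (size_t i = 0; i < take; ++i)
      v = v * 4294967296.0L + (long double)m[len - 1 - i];
    ex = 32L * (long)(len - take);
    return v;
  };
  long ea, eb;
  long double va = lead(a.mag, ea), vb = lead(b.mag, eb);
  long double q = va / vb;
  long shift = ea - eb;
  double out = (double)(q * std::pow(2.0L, (long double)shift));
  return a.sign * b.sign < 0 ? -out : out;
}
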