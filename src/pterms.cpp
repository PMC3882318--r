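// Numerically distinct implementations of the binomial correction term
//   P(n, k; p) = C(n,k) * p^k * (1-p)^(n-k)
// used to build the P lookup tables and to cross-check each other over the
// full (n, k) range at very small p, where naive evaluation mixes huge
// binomial coefficients with severely underflowing powers.
//
// Variants:
//   org     - interleaved product: one coefficient factor (n-k+j)/j, one p
//             factor and one (1-p) factor per loop step, leftover (1-p)
//             powers appended; intermediates stay near the final magnitude.
//   choose  - exact integer factorials: n! built in arbitrary precision,
//             divided exactly by the factors of k! and (n-k)!, converted to
//             double, then scaled by the probability powers.
//   comb    - exact multiplicative coefficient: C(n,k) by the integer
//             recurrence C(n,j) = C(n,j-1)*(n-j+1)/j in arbitrary precision
//             (every intermediate division is exact), then scaled.
//   comb2   - log-gamma: exp(lgamma-based log coefficient + k*log(p) +
//             (n-k)*log1p(-p)).
//   logReal - base-10 logarithmic version of the interleaving: the same
//             factor stream accumulated as log10, then exponentiated.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// ---- minimal arbitrary-precision unsigned integer, base 2^32 -------------

typedef std::vector<uint32_t> BigInt; // little-endian limbs, no leading zeros

static void big_mul_small(BigInt &a, uint32_t m) {
    uint64_t carry = 0;
    for (std::size_t i = 0; i < a.size(); ++i) {
        uint64_t cur = (uint64_t)a[i] * m + carry;
        a[i] = (uint32_t)cur;
        carry = cur >> 32;
    }
    while (carry) {
        a.push_back((uint32_t)carry);
        carry >>= 32;
    }
}

// division by a small divisor; exact whenever the caller guarantees d | a
static void big_div_small(BigInt &a, uint32_t d) {
    uint64_t rem = 0;
    for (std::size_t i = a.size(); i-- > 0;) {
        uint64_t cur = (rem << 32) | a[i];
        a[i] = (uint32_t)(cur / d);
        rem = cur % d;
    }
    while (a.size() > 1 && a.back() == 0) a.pop_back();
}

static double big_to_double(const BigInt &a) {
    long double acc = 0.0L;
    for (std::size_t i = a.size(); i-- > 0;)
        acc = acc * 4294967296.0L + (long double)a[i];
    return (double)acc;
}

// exact C(n,k) via n! / (k! (n-k)!), all divisions by small scalars
static double choose_coef(const BigInt &fact_n, int k, int nk) {
    BigInt v(fact_n);
    for (int j = 2; j <= k; ++j) big_div_small(v, (uint32_t)j);
    for (int j = 2; j <= nk; ++j) big_div_small(v, (uint32_t)j);
    return big_to_double(v);
}

static BigInt factorial_big(int n) {
    BigInt f(1, 1u);
    for (int j = 2; j <= n; ++j) big_mul_small(f, (uint32_t)j);
    return f;
}

// ---- the five P-term variants --------------------------------------------

static double p_org(int n, int k, double p) {
    const double q = 1.0 - p;
    const int nk = n - k;
    double r = 1.0;
    for (int j = 1; j <= k; ++j) {
        r *= (double)(nk + j) / (double)j;
        r *= p;
        if (j <= nk) r *= q;
    }
    for (int j = k + 1; j <= nk; ++j) r *= q;
    return r;
}

static double p_logreal(int n, int k, double p) {
    if (k > 0 && p == 0.0) return 0.0;
    const double q = 1.0 - p;
    const int nk = n - k;
    double s = 0.0;
    for (int j = 1; j <= k; ++j) {
        s += std::log10((double)(nk + j) / (double)j);
        s += std::log10(p);
        if (j <= nk) s += std::log10(q);
    }
    for (int j = k + 1; j <= nk; ++j) s += std::log10(q);
    return std::pow(10.0, s);
}

static double p_comb2(int n, int k, double p) {
    if (k > 0 && p == 0.0) return 0.0;
    double lc = std::lgamma((double)n + 1.0) - std::lgamma((double)k + 1.0) -
                std::lgamma((double)(n - k) + 1.0);
    double lp = (k > 0) ? (double)k * std::log(p) : 0.0;
    double lq = (n - k > 0) ? (double)(n - k) * std::log1p(-p) : 0.0;
    return std::exp(lc + lp + lq);
}

static double p_choose(int n, int k, double p) {
    BigInt f = factorial_big(n);
    double coef = choose_coef(f, k, n - k);
    return coef * std::pow(p, (double)k) * std::pow(1.0 - p, (double)(n - k));
}

static double p_comb(int n, int k, double p) {
    BigInt c(1, 1u);
    for (int j = 1; j <= k; ++j) {
        big_mul_small(c, (uint32_t)(n - j + 1));
        big_div_small(c, (uint32_t)j); // exact: C(n,j) is an integer
    }
    double coef = big_to_double(c);
    return coef * std::pow(p, (double)k) * std::pow(1.0 - p, (double)(n - k));
}

static int method_id(const std::string &method) {
    if (method == "org") return 0;
    if (method == "choose") return 1;
    if (method == "comb") return 2;
    if (method == "comb2") return 3;
    if (method == "logReal") return 4;
    stop("unknown binomial method '%s'", method.c_str());
    return -1; // unreachable
}

// [[Rcpp::export]]
double cpp_p_term(int n, int k, double p, std::string method) {
    if (n < 0 || k < 0 || k > n) stop("require 0 <= k <= n");
    if (p < 0.0 || p >= 1.0) stop("require 0 <= p < 1");
    switch (method_id(method)) {
    case 0: return p_org(n, k, p);
    case 1: return p_choose(n, k, p);
    case 2: return p_comb(n, k, p);
    case 3: return p_comb2(n, k, p);
    default: return p_logreal(n, k, p);
    }
}

// Full table P[n+1][k+1] for 0 <= k <= n <= nmax (upper triangle zero).
// [[Rcpp::export]]
NumericMatrix cpp_p_matrix(int nmax, double p, std::string method) {
    if (nmax < 0) stop("require nmax >= 0");
    if (p < 0.0 || p >= 1.0) stop("require 0 <= p < 1");
    const int id = method_id(method);
    NumericMatrix out(nmax + 1, nmax + 1);

    if (id == 1) { // choose: grow n! incrementally, divide per (n,k)
        BigInt f(1, 1u);
        for (int n = 0; n <= nmax; ++n) {
            if (n > 1) big_mul_small(f, (uint32_t)n);
            // coefficient is symmetric in k <-> n-k: compute one half
            std::vector<double> coef(n + 1);
            for (int k = 0; k <= n / 2; ++k) {
                double c = (k == 0) ? 1.0 : choose_coef(f, k, n - k);
                coef[k] = c;
                coef[n - k] = c;
            }
            for (int k = 0; k <= n; ++k)
                out(n, k) = coef[k] * std::pow(p, (double)k) *
                            std::pow(1.0 - p, (double)(n - k));
        }
        return out;
    }

    if (id == 2) { // comb: exact multiplicative recurrence along each row
        for (int n = 0; n <= nmax; ++n) {
            BigInt c(1, 1u);
            out(n, 0) = std::pow(1.0 - p, (double)n);
            for (int k = 1; k <= n; ++k) {
                big_mul_small(c, (uint32_t)(n - k + 1));
                big_div_small(c, (uint32_t)k);
                out(n, k) = big_to_double(c) * std::pow(p, (double)k) *
                            std::pow(1.0 - p, (double)(n - k));
            }
        }
        return out;
    }

    for (int n = 0; n <= nmax; ++n) {
        for (int k = 0; k <= n; ++k) {
            double v;
            switch (id) {
            case 0: v = p_org(n, k, p); break;
            case 3: v = p_comb2(n, k, p); break;
            default: v = p_logreal(n, k, p); break;
            }
            out(n, k) = v;
        }
    }
    return out;
}
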