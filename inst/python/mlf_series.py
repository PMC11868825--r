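#!/usr/bin/env python
"""Extended-precision partial sums of the two-parameter Mittag-Leffler series.

Reads a whitespace-separated table from the file given as argv[1], one
evaluation request per line:

    z alpha gamma n_terms precision_digits

and prints one result line per request:

    ok <value>        -- partial sum, accurate to `precision_digits`
    err <message>     -- divergence or invalid input

The series sum_k z^k / Gamma(alpha*k + gamma) is summed with the reciprocal
gamma convention (1/Gamma at a pole is 0).  The working precision is raised
above `precision_digits` by the estimated cancellation (max term magnitude
over result magnitude), so the returned double/decimal string is accurate to
the requested digits even deep in the cancellation-dominated regime
(e.g. alpha=0.5, z=-50 needs ~1100 working digits).

Terms are generated with a stride-q recurrence when alpha = p/q is an exact
small rational (t_{k+q} = t_k * z^q / ((x)(x+1)...(x+p-1)), x = alpha*k+gamma),
falling back to direct rgamma evaluation otherwise; the first terms (where
Gamma poles can occur for gamma <= 0) are always evaluated directly.
"""
import sys
import math
from fractions import Fraction

from mpmath import mp, mpf, rgamma


def _max_term_log10(z, alpha, gamma, kmax):
    """Estimate log10 of the largest series term magnitude in doubles."""
    if z == 0.0:
        return 0.0
    la = math.log(abs(z))
    best = 0.0
    k = 0
    while k <= kmax:
        x = alpha * k + gamma
        if x > 0:
            t = k * la - math.lgamma(x)
            if t > best:
                best = t
            # terms decrease forever once lgamma growth dominates
            if t < best - 60:
                break
        k += 1
    return best / math.log(10.0)


def partial_sum(z, alpha, gamma, n_terms, digits):
    if abs(z) > 50:
        raise ValueError("series oracle restricted to |z| <= 50")
    if z == 0.0:
        mp.dps = digits + 10
        return rgamma(mpf(repr(gamma)))
    cancel = _max_term_log10(z, alpha, gamma, max(n_terms, 200000))
    mp.dps = int(digits + cancel + 25)
    zz = mpf(repr(z))
    al = mpf(repr(alpha))
    ga = mpf(repr(gamma))

    frac = Fraction(alpha).limit_denominator(1000)
    exact_rational = abs(float(frac) - alpha) < 1e-15
    q = frac.denominator if exact_rational else 0
    p = frac.numerator if exact_rational else 0

    # direct evaluation up to k0 (covers all possible Gamma poles), then
    # stride-q recurrence chains when alpha is rational
    k0 = int(math.ceil(max(0.0, (1.0 - gamma) / alpha))) + (q if q else 0) + 2

    # tolerance in log2 magnitude units (mp.mag is cheap: ceil(log2 |x|))
    tol_mag = -int((digits + 10) * 3.3220)
    total = mpf(0)
    terms = {}          # recent terms per residue class, for the recurrence
    zq = zz ** q if exact_rational else None
    prev_mag = None
    decreasing_tail = 0
    k = 0
    zpow = mpf(1)
    while True:
        if k <= k0 or not exact_rational:
            t = zpow * rgamma(al * k + ga)
            zpow *= zz
        else:
            tprev = terms[k - q]
            x = al * (k - q) + ga
            denom = mpf(1)
            for j in range(p):
                denom *= (x + j)
            t = tprev * zq / denom
        terms[k] = t
        if exact_rational and (k - q - 1) in terms:
            del terms[k - q - 1]
        total += t
        if t != 0:
            m = mp.mag(t)
            if prev_mag is not None:
                decreasing_tail = decreasing_tail + 1 if m <= prev_mag else 0
            prev_mag = m
            msum = mp.mag(total) if total != 0 else 0
            if m < msum + tol_mag and decreasing_tail >= 3 and k > 4:
                return total
        k += 1
        if k >= n_terms:
            if prev_mag is not None and total != 0 and \
               prev_mag < mp.mag(total) + tol_mag:
                return total
            if decreasing_tail == 0:
                raise ArithmeticError(
                    "series not converged after %d terms (terms not decreasing)"
                    % n_terms)
            return total


def main():
    out = []
    with open(sys.argv[1]) as fh:
        for line in fh:
            line = line.strip()
            if not line or line.startswith("#"):
                continue
            z_s, a_s, g_s, n_s, d_s = line.split()
            try:
                z, a, g = float(z_s), float(a_s), float(g_s)
                n, d = int(n_s), int(d_s)
                if not (a > 0):
                    raise ValueError("alpha must be > 0")
                val = partial_sum(z, a, g, n, d)
                out.append("ok " + mp.nstr(val, min(d, 30),
                                           strip_zeros=False))
            except (ArithmeticError, ValueError) as e:
                out.append("err " + str(e).replace("\n", " "))
    sys.stdout.write("\n".join(out) + "\n")


if __name__ == "__main__":
    main()
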