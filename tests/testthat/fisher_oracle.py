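"""Exact-integer enumeration oracle for the two-sided Fisher test.

Reads a CSV of 2x2 tables (a,b,c,d per line) and prints one two-sided
p-value per line. All comparisons between table probabilities are done on
exact integer numerators (the common denominator C(N, k) cancels), so the
"sum of probabilities at most as likely as observed" rule is evaluated
without any floating-point tie ambiguity.
"""
import sys
from math import comb

with open(sys.argv[1]) as fh:
    for line in fh:
        line = line.strip()
        if not line:
            continue
        a, b, c, d = (int(x) for x in line.split(","))
        r1, r2, k = a + b, c + d, a + c
        lo, hi = max(0, k - r2), min(r1, k)
        nums = [comb(r1, x) * comb(r2, k - x) for x in range(lo, hi + 1)]
        obs = comb(r1, a) * comb(r2, k - a)
        p = sum(n for n in nums if n <= obs) / comb(r1 + r2, k)
        print(repr(min(1.0, p)))
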