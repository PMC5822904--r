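#!/usr/bin/env python
"""Generate the frozen oracle grid for the binomial point probability.

Evaluates log P, P = C(N,n) f^n (1-f)^(N-n), with exact rational arithmetic
(sympy), then takes the log at 30 significant digits. The resulting TSV is
committed as tests/testthat/fixtures/binom-oracle.tsv and compared against
the package's log-space implementation with tolerance 1e-9 on |delta log P|.

Run from the repository root:  python tools/make-binom-oracle.py
"""
import itertools
from sympy import Rational, binomial, log

NS = [1, 2, 5, 10, 20, 50, 100, 200, 500, 1000, 2000, 5000, 10000]
FS = [Rational(1, 100000), Rational(1, 10000), Rational(1, 1000),
      Rational(1, 100), Rational(1, 10), Rational(1, 2)]

rows = []
for N, f in itertools.product(NS, FS):
    picks = sorted({0, 1, 2, min(5, N), min(10, N), N // 2, N - 1, N})
    for n in picks:
        if n < 0 or n > N:
            continue
        P = binomial(N, n) * f**n * (1 - f)**(N - n)
        logp = log(P).evalf(30)
        rows.append((n, N, float(f), f"{logp}"))

with open("tests/testthat/fixtures/binom-oracle.tsv", "w") as fh:
    fh.write("n\tN\tf\tlog_p\n")
    for n, N, fv, lp in rows:
        fh.write(f"{n}\t{N}\t{fv:.10g}\t{lp}\n")
print(f"wrote {len(rows)} oracle points")
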