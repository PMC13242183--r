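#!/usr/bin/env python
"""Arbitrary-precision oracle for the fusion weight worked values.

Evaluates alpha = |e^accC - e^accR| * k and the softmax weights
w_R = e^(alpha*accR) / (e^(alpha*accR) + e^(alpha*accC)) at 50 decimal
digits with mpmath, for the accuracy pairs used in the worked-value
tests. The printed values are frozen into tests/testthat/test-fusion.R
and test-acceptance.R; run this before touching those constants.
"""
from mpmath import mp, mpf, exp, fabs

mp.dps = 50


def alpha(acc_r, acc_c, k):
    return fabs(exp(acc_c) - exp(acc_r)) * k


def weights(acc_r, acc_c, a):
    e_r, e_c = exp(a * acc_r), exp(a * acc_c)
    return e_r / (e_r + e_c), e_c / (e_r + e_c)


for acc_r, acc_c in [(mpf("0.954"), mpf("0.892")), (mpf("1.0"), mpf("0.5"))]:
    a = alpha(acc_r, acc_c, 10)
    w_r, w_c = weights(acc_r, acc_c, a)
    print(f"acc_rna={acc_r}, acc_cnv={acc_c}, k=10")
    print(f"  alpha = {mp.nstr(a, 20)}")
    print(f"  w_rna = {mp.nstr(w_r, 20)}")
    print(f"  w_cnv = {mp.nstr(w_c, 20)}")
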