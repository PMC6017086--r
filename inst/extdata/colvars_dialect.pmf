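# 1
#      2.0000000e+00    1.0000000e-01          120 0
# temperature=300
  2.0500000e+00   4.1250000e+00
  2.1500000e+00   3.2000000e+00
  2.2500000e+00   2.4050000e+00
  2.3500000e+00   1.7200000e+00
  2.4500000e+00   1.1450000e+00
  2.5500000e+00   6.8000000e-01
  2.6500000e+00   3.2500000e-01
  2.7500000e+00   8.0000000e-02
  2.8500000e+00   0.0000000e+00
  2.9500000e+00   3.0000000e-02
  3.0500000e+00   1.7000000e-01
  3.1500000e+00   4.2000000e-01
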