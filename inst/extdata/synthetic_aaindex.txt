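H SYNH000001
D Synthetic test scale in AAindex flat-file format (synthetic values)
R
A Synthetic, A.
T Synthetic scale for format-parser tests
J Unpublished
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  0.73  1.07  0.87  0.74 -0.58 -1.62 -0.15 -1.99  0.32 -0.44
  0.44  0.20  0.28  0.88  0.91 -0.62 -0.01  1.01 -0.15 -0.97
//
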