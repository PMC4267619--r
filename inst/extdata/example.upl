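  20 ASN  HD21  158 ADE  N1    3.20
  24 ASN  H     158 ADE  N3    3.30
  35 SER  O     158 ADE  H61   3.10
  36 THR  HG1   158 ADE  N7    2.90
  36 THR  HA     36 THR  HB    2.80
  36 THR  H      37 LEU  H     4.00
  10 ALA  HA     13 GLY  H     5.00
   5 TRP  HE1    60 LEU  HD1   5.50
  12 GLY  H      16 ALA  O     2.20  #HB
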