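      Assignment         w1         w2
      N366N-H       117.402      8.215   1.1e6
      N370N-H       112.804      7.902   1.4e6
      W380N-H       129.101      9.871   2.2e6
      S381N-H       115.220      8.433   1.0e6
      T382N-H       119.233      8.314   1.5e6
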