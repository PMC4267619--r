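      Assignment         w1         w2
      N366N-H       117.650      8.201   1.0e6
      N370N-H       113.911      7.780   1.2e6
      W380N-H       130.215      9.995   2.0e6
      S381N-H       115.455      8.470   0.9e6
      T382N-H       119.501      8.390   1.3e6
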