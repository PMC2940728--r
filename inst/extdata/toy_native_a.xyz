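8
toy compact (native) structure frame 0
CA                   3                 0                 0
CA              -0.521             2.954               1.1
CA              -2.819            -1.026               2.2
CA                 1.5            -2.598               3.3
CA               2.298             1.928               4.4
CA              -2.298             1.928               5.5
CA                -1.5            -2.598               6.6
CA               2.819            -1.026               7.7
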