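8
toy extended (denatured) structure frame 0
CA                   0                 0                 0
CA                   0                 0               2.8
CA                   0                 0               5.6
CA                   0                 0               8.4
CA                   0                 0              11.2
CA                   0                 0                14
CA                   0                 0              16.8
CA                   0                 0              19.6
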