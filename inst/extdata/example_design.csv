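"condition","onset","duration","session_length","sampling_rate"
"NV",2,9,690,10
"V",27.4700114226273,9,690,10
"V",50.7792781339678,9,690,10
"NV",78.5964100038621,9,690,10
"V",105.296294662036,9,690,10
"NV",132.880470392952,9,690,10
"NV",155.639405074773,9,690,10
"NV",182.727703082606,9,690,10
"V",207.619309009637,9,690,10
"NV",235.391253479654,9,690,10
"NV",261.940632086094,9,690,10
"NV",289.4453093836,9,690,10
"V",315.33362084024,9,690,10
"V",341.05799601983,9,690,10
"V",368.607835721927,9,690,10
"V",390.771873741532,9,690,10
"NV",416.127203383138,9,690,10
"V",443.275986274944,9,690,10
"NV",470.146473059895,9,690,10
"NV",495.504541616287,9,690,10
"V",523.55957020093,9,690,10
"V",548.639762161716,9,690,10
"V",572.360893372812,9,690,10
"NV",594.857826653635,9,690,10
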