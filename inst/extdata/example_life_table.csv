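age,qx
40,0.0017
41,0.0018
42,0.0020
43,0.0021
44,0.0023
45,0.0025
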