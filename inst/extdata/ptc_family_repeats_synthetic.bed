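11	74167150	74167300
X	66765100	66765200
17	26521950	26522100
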