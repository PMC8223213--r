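frames analyzed: 12 (stride 1)
final complex ratio: 1
final average aggregation number: 8
final contacts: CM15=NA SUR=NA
focal aggregate growth events (frame, +gained/-lost):
  frame 5: +4/-0 (size 8)
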