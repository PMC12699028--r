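instrument: SSSQ
items:
- index: 1
  subscale: distress
  reverse: no
- index: 2
  subscale: distress
  reverse: no
- index: 3
  subscale: distress
  reverse: no
- index: 4
  subscale: distress
  reverse: no
- index: 5
  subscale: worry
  reverse: no
- index: 6
  subscale: worry
  reverse: no
- index: 7
  subscale: worry
  reverse: no
- index: 8
  subscale: worry
  reverse: no
- index: 9
  subscale: confidence
  reverse: no
- index: 10
  subscale: confidence
  reverse: no
- index: 11
  subscale: confidence
  reverse: no
- index: 12
  subscale: confidence
  reverse: no
- index: 13
  subscale: negative_affect
  reverse: no
- index: 14
  subscale: negative_affect
  reverse: no
- index: 15
  subscale: negative_affect
  reverse: no
- index: 16
  subscale: negative_affect
  reverse: no
- index: 17
  subscale: motivation
  reverse: no
- index: 18
  subscale: motivation
  reverse: no
- index: 19
  subscale: motivation
  reverse: no
- index: 20
  subscale: motivation
  reverse: no
- index: 21
  subscale: self_evaluation
  reverse: no
- index: 22
  subscale: self_evaluation
  reverse: no
- index: 23
  subscale: self_evaluation
  reverse: no
- index: 24
  subscale: self_evaluation
  reverse: no
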