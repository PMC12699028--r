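instrument: PANAS
items:
- index: 1
  subscale: positive
  reverse: no
- index: 2
  subscale: negative
  reverse: no
- index: 3
  subscale: positive
  reverse: no
- index: 4
  subscale: negative
  reverse: no
- index: 5
  subscale: positive
  reverse: no
- index: 6
  subscale: negative
  reverse: no
- index: 7
  subscale: negative
  reverse: no
- index: 8
  subscale: negative
  reverse: no
- index: 9
  subscale: positive
  reverse: no
- index: 10
  subscale: positive
  reverse: no
- index: 11
  subscale: negative
  reverse: no
- index: 12
  subscale: positive
  reverse: no
- index: 13
  subscale: negative
  reverse: no
- index: 14
  subscale: positive
  reverse: no
- index: 15
  subscale: negative
  reverse: no
- index: 16
  subscale: positive
  reverse: no
- index: 17
  subscale: positive
  reverse: no
- index: 18
  subscale: negative
  reverse: no
- index: 19
  subscale: positive
  reverse: no
- index: 20
  subscale: negative
  reverse: no
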