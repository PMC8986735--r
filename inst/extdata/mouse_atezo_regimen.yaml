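- agent: antibody
  route: IP
  time: 1.0
  amount: 5.0
- agent: antibody
  route: IP
  time: 1.71
  amount: 5.0
- agent: antibody
  route: IP
  time: 2.43
  amount: 5.0
- agent: antibody
  route: IP
  time: 3.14
  amount: 5.0
- agent: antibody
  route: IP
  time: 3.86
  amount: 5.0
- agent: antibody
  route: IP
  time: 4.57
  amount: 5.0
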