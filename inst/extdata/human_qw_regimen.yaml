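- agent: miRNA_NP
  route: IV_bolus
  time: 80.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 81.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 82.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 83.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 84.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 85.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 86.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 87.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 88.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 89.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 90.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 91.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 92.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 93.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 94.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 95.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 96.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 97.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 98.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 99.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 100.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 101.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 102.0
  amount: 0.026
- agent: miRNA_NP
  route: IV_bolus
  time: 103.0
  amount: 0.026
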