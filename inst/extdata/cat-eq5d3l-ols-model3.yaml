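name: cat-eq5d3l-ols-model3
intercept: 1.0661
coefficients:
  q3: 0.0103
  q4: 0.0120
  q5: 0.0168
  q6: 0.0255
  q8: 0.0125
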