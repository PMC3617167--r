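variable,mean,ci_low,ci_high,range_low,range_high
age,108,106,110,97,119
va_span,4.1,3.9,4.2,2.8,5
C,24.6,22.5,26.6,9.3,41.4
K,3.6,3.5,3.8,2.4,4.8
reading_speed,80,74,86,37,130
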