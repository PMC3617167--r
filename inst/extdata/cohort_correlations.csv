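variable,age,va_span,C,K,reading_speed
age,1,0.30,0.39,0.19,0.40
va_span,0.30,1,0.67,0.67,0.56
C,0.39,0.67,1,0.54,0.50
K,0.19,0.67,0.54,1,0.34
reading_speed,0.40,0.56,0.50,0.34,1
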