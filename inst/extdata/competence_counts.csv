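label,positives,total
wild_type_0.65h,1,15000
wild_type_3.4h,30,23000
spo0A_null_0.65h,0,30000
spo0A_null_3.4h,0,33000
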