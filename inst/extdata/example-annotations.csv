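record_id,onset_s,offset_s
rec01,2996,3036
rec01,8721,8759
rec02,1467,1494
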