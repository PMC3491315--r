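activity,walking,standing,holding,sitting,not_wearing
walking,908,0,0,0,0
standing,0,708,4,8,0
holding,2,22,768,0,4
sitting,4,32,48,652,0
not_wearing,0,0,4,4,220
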