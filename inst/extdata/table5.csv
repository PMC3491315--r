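activity,walking,standing,holding,sitting,not_wearing
walking,900,4,0,0,4
standing,8,676,0,36,0
holding,0,88,624,40,44
sitting,4,120,120,492,0
not_wearing,0,0,8,0,220
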