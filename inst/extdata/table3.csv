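activity,walking,standing,holding,sitting,not_wearing
walking,662,0,6,10,34
standing,0,400,0,16,0
holding,4,0,376,32,4
sitting,10,24,2,396,4
not_wearing,8,0,12,4,180
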