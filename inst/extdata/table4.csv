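activity,walking,standing,holding,sitting,not_wearing
walking,428,96,44,120,24
standing,0,308,36,72,0
holding,36,0,180,184,16
sitting,0,56,104,276,0
not_wearing,0,0,48,32,124
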