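activity,walking,standing,holding,sitting,not_wearing
walking,588,8,80,4,32
standing,8,400,4,4,0
holding,20,4,296,56,40
sitting,8,84,132,208,4
not_wearing,0,0,56,0,148
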