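"recumbency","BrP1","BrP2","BrP3","BrP4"
"dorsal",5,0,1,4
"ventral",2,1,3,4
"right_lateral",0,1,7,1
"left_lateral",0,2,8,0
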