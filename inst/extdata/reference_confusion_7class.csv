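"","Akiec","BCC","BKL","Df","Mel","Nv","Vasc"
"Akiec",42,0,2,0,0,1,0
"BCC",0,43,0,0,0,0,2
"BKL",1,0,42,0,0,2,0
"Df",0,0,1,44,0,0,0
"Mel",0,0,0,0,45,0,0
"Nv",0,0,2,0,0,43,0
"Vasc",0,0,0,0,0,0,45
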