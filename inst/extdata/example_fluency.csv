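id,listnum,item,category
A101,1,hamster,animals
A101,1,cat,animals
A101,1,dog,animals
A101,1,wolf,animals
A101,1,coyote,animals
A101,1,zebru,animals
A101,2,lion,animals
A101,2,hippo,animals
A101,2,giraffe,animals
A101,2,african elephant,animals
A101,2,asian elephant,animals
A102,1,eagle,animals
A102,1,sparrow,animals
A102,1,owl,animals
A102,1,eagle,animals
A102,1,unicorn,animals
A102,2,dog,animals
A102,2,fox,animals
A102,2,goldfish,animals
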