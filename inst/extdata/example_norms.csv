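cat,39.04
dog,59.45
wolf,10.24
zebra,1.51
lion,15.29
hippo,1.53
giraffe,1.33
elephant,9.16
eagle,6.49
sparrow,1.18
owl,4.29
hamster,2.24
coyote,3.92
fox,13.51
goldfish,2.12
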