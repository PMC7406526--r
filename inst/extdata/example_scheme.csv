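Pets,hamster
Pets,cat
Pets,dog
Pets,goldfish
Canines,dog
Canines,wolf
Canines,coyote
Canines,fox
ZooAnimals,zebra
ZooAnimals,lion
ZooAnimals,hippo
ZooAnimals,giraffe
ZooAnimals,elephant
Birds,eagle
Birds,sparrow
Birds,owl
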