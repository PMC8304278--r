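sample,matrix_type,group,ortho,pyro,trimeta,tri,longchain,scd
minced beef,meat,fresh meat,781,ND,ND,ND,ND,ND
beef hamburger,meat,fresh meat,863,<LOD,ND,ND,ND,ND
chicken muscle,meat,fresh meat,765,<LOD,<LOD,<LOQ,ND,ND
turkey muscle,meat,fresh meat,1000,ND,ND,ND,ND,ND
baked turkey muscle I,meat,processed meat,839,<LOD,0.28,ND,ND,ND
baked turkey muscle II,meat,processed meat,1105,0.11,8,0.32,hexametaphosphate,ND
pre-cooked tripe,meat,processed meat,453,2.0,ND,0.9,tetrametaphosphate,ND
cooked meat,meat,processed meat,855,0.19,<LOD,0.08,ND,ND
meat loaf,meat,processed meat,846,<LOD,ND,ND,ND,ND
cooked ham,meat,processed meat,931,<LOD,3,0.7,ND,detected
mortadella I,meat,processed meat,921,0.67,<LOD,0.3,ND,ND
mortadella II,meat,processed meat,847,0.24,ND,0.8,ND,ND
mortadella III,meat,processed meat,791,<LOD,0.21,ND,ND,ND
mortadella IV,meat,processed meat,785,<LOD,0.22,ND,ND,ND
wurstel I,meat,processed meat,902,91,11,5,tetrametaphosphate;pentaphosphate,detected
wurstel II,meat,processed meat,6094,5,<LOD,<LOD,ND,ND
wurstel III,meat,processed meat,4694,117,ND,857,ND,detected
pasta with meat sauce I,meat,processed meat,647,0.70,<LOD,<LOD,ND,ND
pasta with meat sauce II,meat,processed meat,830,<LOD,0.21,ND,ND,ND
cuttlefish I,fish,fish,97,<LOD,<LOD,9,ND,ND
cuttlefish II,fish,fish,944,<LOD,<LOD,0.21,ND,ND
sea bass,fish,fish,987,<LOD,<LOD,<LOQ,ND,ND
sea bream,fish,fish,1159,0.33,<LOD,0.72,ND,ND
swordfish,fish,fish,1299,<LOD,<LOD,1.0,ND,ND
yellowfin tuna,fish,fish,895,<LOD,ND,ND,ND,ND
salmon fillets,fish,fish,869,<LOD,0.32,ND,ND,ND
tilapia fillet,fish,fish,652,<LOD,<LOD,ND,ND,ND
cod burgers,fish,fish,1024,<LOD,ND,0.3,ND,ND
shelled mussels,fish,seafood,141,7,<LOD,3,pentaphosphate,detected
shrimps,fish,seafood,967,<LOD,0.17,ND,ND,ND
squid,fish,seafood,1187,0.21,<LOD,0.19,ND,ND
caramote prawn I,fish,seafood,9578,ND,9,3,tetraphosphate;pentametaphosphate;pentaphosphate;hexaphosphate,detected
caramote prawn II,fish,seafood,12554,<LOQ,ND,9,tetraphosphate;pentametaphosphate;pentaphosphate;hexaphosphate,detected
caramote prawn III,fish,seafood,6585,<LOQ,5,ND,tetraphosphate;pentametaphosphate;pentaphosphate;hexaphosphate,detected
milk UHT I,dairy,milk,681,16,ND,0.57,ND,ND
milk UHT II,dairy,milk,554,ND,<LOD,<LOD,ND,ND
butter I,dairy,butter,33,ND,ND,ND,ND,ND
butter II,dairy,butter,663,ND,ND,<LOQ,ND,ND
butter III,dairy,butter,462,ND,<LOD,<LOQ,ND,ND
butter IV,dairy,butter,786,ND,<LOD,<LOQ,ND,ND
ripened cheese,dairy,cheese,370,ND,ND,<LOD,ND,ND
seasoned cheese,dairy,cheese,592,ND,<LOD,ND,ND,ND
fresh stracchino cheese,dairy,cheese,2715,ND,ND,49,tetraphosphate;tetrametaphosphate;pentaphosphate;hexametaphosphate;hexaphosphate,ND
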