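species,total,identified,Jan,Feb,Mar,Apr,May,Jun,Jul,Aug,Sep,Oct,Nov,Dec
Brown-eared bulbul,1190,1116,234,173,179,118,43,44,41,42,34,39,88,155
Eurasian tree sparrow,989,461,115,71,55,66,102,83,69,69,94,83,93,89
White-cheeked starling,826,267,107,87,69,60,116,119,59,42,49,27,36,55
Japanese white-eye,782,580,149,92,109,65,32,26,16,11,24,69,83,106
Japanese pygmy woodpecker,748,96,124,89,89,75,56,43,23,14,29,62,58,86
Great tit,708,279,107,72,83,47,74,43,24,25,38,53,57,85
Oriental turtle dove,566,149,89,69,55,53,53,25,21,11,34,40,49,67
Grey-capped greenfinch,504,270,70,67,45,48,50,41,29,20,13,38,28,55
Carrion crow,497,227,50,42,37,54,58,41,22,37,34,31,47,44
Varied tit,438,272,59,38,45,40,26,20,10,9,41,70,37,43
Meadow bunting,417,155,86,77,66,26,14,20,7,8,8,16,38,51
Bull-headed shrike,371,241,86,49,43,22,10,4,7,5,12,26,41,66
Large-billed crow,363,257,35,29,31,25,33,27,23,18,27,37,38,40
Long-tailed tit,280,68,56,41,32,16,22,12,11,2,11,25,20,32
Azure-winged magpie,129,95,16,13,6,7,4,8,7,8,12,9,13,26
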