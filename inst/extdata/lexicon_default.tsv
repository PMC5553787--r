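term|kind|category|device_class|generation|polymer
lad|vessel|LAD|none|none|none
di|vessel|LAD|none|none|none
d1|vessel|LAD|none|none|none
d2|vessel|LAD|none|none|none
diagonal|vessel|LAD|none|none|none
dx|vessel|LAD|none|none|none
lcx|vessel|LCx|none|none|none
om|vessel|LCx|none|none|none
ri|vessel|LCx|none|none|none
ramus|vessel|LCx|none|none|none
lm|vessel|LM|none|none|none
lm-lad|vessel|LM|none|none|none
lm-lcx|vessel|LM|none|none|none
rca|vessel|RCA|none|none|none
pda|vessel|RCA|none|none|none
plv|vessel|RCA|none|none|none
plb|vessel|RCA|none|none|none
vision|stent|Vision|BMS|none|none
genoss|stent|Genoss|BMS|none|none
coroflex blue|stent|Coroflex Blue|BMS|none|none
zeta|stent|Zeta|BMS|none|none
cypher|stent|Cypher|DES|first|none
cypher select|stent|Cypher|DES|first|none
coroflex please|stent|Coroflex Please|DES|first|none
taxus|stent|Taxus|DES|first|none
taxus liberte|stent|Taxus|DES|first|none
resolute|stent|Resolute family|DES|second|durable
resolute integrity|stent|Resolute family|DES|second|durable
resolute onyx|stent|Resolute family|DES|second|durable
promus|stent|Promus family|DES|second|durable
promus element|stent|Promus family|DES|second|durable
promus premier|stent|Promus family|DES|second|durable
xience|stent|Xience family|DES|second|durable
xience v|stent|Xience family|DES|second|durable
xience prime|stent|Xience family|DES|second|durable
xience xpedition|stent|Xience family|DES|second|durable
endeavor|stent|Endeavor|DES|second|durable
endeavor sprint|stent|Endeavor|DES|second|durable
biomatrix|stent|Biomatrix|DES|second|biodegradable
biomatrix flex|stent|Biomatrix|DES|second|biodegradable
desyne|stent|Desyne|DES|second|biodegradable
nobori|stent|Nobori|DES|second|biodegradable
orsiro|stent|Orsiro|DES|second|biodegradable
nc trek|balloon|NC Trek|none|none|none
nc sprinter|balloon|NC Sprinter|none|none|none
nc euphora|balloon|NC Euphora|none|none|none
quantum maverick|balloon|Quantum Maverick|none|none|none
pantera leo|balloon|Pantera Leo|none|none|none
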