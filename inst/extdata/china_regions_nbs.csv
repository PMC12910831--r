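dmu,region
Beijing,east
Tianjin,east
Hebei,east
Liaoning,east
Shanghai,east
Jiangsu,east
Zhejiang,east
Fujian,east
Shandong,east
Guangdong,east
Hainan,east
Shanxi,central
Jilin,central
Heilongjiang,central
Anhui,central
Jiangxi,central
Henan,central
Hubei,central
Hunan,central
Inner Mongolia,west
Guangxi,west
Chongqing,west
Sichuan,west
Guizhou,west
Yunnan,west
Shaanxi,west
Gansu,west
Qinghai,west
Ningxia,west
Xinjiang,west
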