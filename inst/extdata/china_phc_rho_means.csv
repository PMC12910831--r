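dmu,mean_rho1,mean_rho2
Beijing,0.99,1.00
Tianjin,1.00,1.00
Hebei,0.82,0.74
Shanxi,0.85,0.84
Inner Mongolia,0.92,0.90
Liaoning,0.89,0.86
Jilin,0.92,0.92
Heilongjiang,0.92,0.89
Shanghai,0.99,1.00
Jiangsu,0.95,0.80
Zhejiang,0.98,0.98
Anhui,0.95,0.84
Fujian,0.94,0.88
Jiangxi,0.95,0.79
Shandong,0.91,0.75
Henan,0.91,0.66
Hubei,0.95,0.74
Hunan,0.93,0.60
Guangdong,0.97,0.90
Guangxi,0.95,0.74
Hainan,0.98,0.98
Chongqing,0.99,0.82
Sichuan,0.95,0.52
Guizhou,0.94,0.82
Yunnan,0.96,0.85
Shaanxi,0.89,0.85
Gansu,0.93,0.89
Qinghai,0.99,0.98
Ningxia,1.00,1.00
Xinjiang,0.95,0.89
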