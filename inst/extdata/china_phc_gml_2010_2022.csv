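dmu,2010,2011,2012,2013,2014,2015,2016,2017,2018,2019,2020,2021
Beijing,1.00,1.00,1.01,1.00,1.00,1.00,1.00,1.00,1.00,0.98,1.01,1.00
Tianjin,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00
Hebei,1.01,1.02,1.02,1.00,1.00,0.99,0.97,0.97,0.99,0.99,1.00,0.98
Shanxi,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00
Inner Mongolia,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00
Liaoning,1.00,1.00,1.00,1.00,1.00,1.00,1.00,0.99,1.00,0.99,1.00,1.00
Jilin,1.00,1.00,1.00,1.00,1.00,1.00,1.00,0.99,1.00,0.99,1.00,1.00
Heilongjiang,0.99,1.00,1.00,1.00,1.00,1.00,1.00,0.99,0.99,1.00,1.00,1.00
Shanghai,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,0.99,1.00,0.99
Jiangsu,1.00,1.01,1.02,1.01,1.01,0.99,1.04,0.96,0.98,0.92,1.00,0.97
Zhejiang,1.01,1.01,1.00,1.00,1.00,1.00,1.00,1.00,1.01,0.97,1.01,1.02
Anhui,1.00,1.03,1.02,1.00,0.99,0.99,1.00,0.99,0.99,0.97,0.99,0.98
Fujian,1.00,1.00,0.99,0.99,1.00,1.00,1.00,1.00,1.00,0.99,1.00,0.99
Jiangxi,1.00,0.94,1.01,0.98,0.99,1.00,1.01,0.99,0.99,0.97,0.99,1.00
Shandong,1.02,1.19,1.00,0.93,0.92,1.01,1.00,0.97,0.95,0.94,1.02,1.01
Henan,1.00,1.05,0.97,1.03,0.99,1.01,1.03,0.96,0.98,0.91,0.98,0.96
Hubei,1.00,1.04,1.00,1.00,0.99,1.01,1.07,0.93,1.07,0.84,1.01,0.99
Hunan,1.01,1.02,1.03,0.97,0.99,1.01,1.00,1.18,1.00,0.81,1.00,1.02
Guangdong,0.98,1.02,1.03,1.00,0.99,1.01,1.00,0.99,1.01,0.86,1.00,0.99
Guangxi,0.97,1.02,1.04,0.96,0.98,0.99,0.99,0.99,1.01,0.96,0.99,1.00
Hainan,1.00,0.92,1.09,1.00,1.00,1.00,1.00,1.00,1.00,0.99,1.00,1.00
Chongqing,1.00,1.03,1.00,0.99,0.98,1.00,1.03,0.98,1.03,0.96,1.01,0.99
Sichuan,0.95,1.13,0.94,0.94,0.97,1.01,1.04,0.96,1.15,0.79,0.99,1.02
Guizhou,0.98,1.02,0.99,0.95,0.98,0.99,0.99,1.00,1.00,0.98,1.01,1.01
Yunnan,0.99,1.01,1.00,0.99,0.99,1.00,0.98,0.99,1.00,0.98,1.00,1.00
Shaanxi,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,0.99,0.99,1.00,1.00
Gansu,1.00,1.00,1.01,1.00,1.00,1.00,1.00,1.00,1.00,0.99,1.00,0.99
Qinghai,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00
Ningxia,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00
Xinjiang,0.99,1.00,1.00,1.00,1.00,1.00,0.99,0.99,1.00,0.99,0.99,1.01
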