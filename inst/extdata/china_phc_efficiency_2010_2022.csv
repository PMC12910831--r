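dmu,2010,2011,2012,2013,2014,2015,2016,2017,2018,2019,2020,2021,2022
Beijing,0.99,0.99,0.99,1.00,1.00,1.00,1.00,1.00,1.00,1.00,0.98,0.99,0.99
Tianjin,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,0.99,0.99,0.99
Hebei,0.75,0.76,0.78,0.80,0.79,0.79,0.79,0.75,0.71,0.70,0.69,0.68,0.66
Shanxi,0.85,0.86,0.86,0.86,0.86,0.86,0.86,0.86,0.85,0.85,0.85,0.85,0.86
Inner Mongolia,0.94,0.93,0.93,0.93,0.93,0.93,0.93,0.92,0.92,0.92,0.91,0.91,0.91
Liaoning,0.89,0.89,0.89,0.90,0.90,0.90,0.89,0.89,0.88,0.89,0.88,0.87,0.88
Jilin,0.94,0.94,0.94,0.94,0.94,0.94,0.94,0.94,0.93,0.93,0.91,0.91,0.91
Heilongjiang,0.93,0.93,0.93,0.94,0.93,0.93,0.93,0.93,0.92,0.91,0.91,0.91,0.91
Shanghai,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,0.98,0.98,0.97
Jiangsu,0.91,0.91,0.93,0.95,0.96,0.97,0.96,1.00,0.96,0.94,0.84,0.84,0.80
Zhejiang,0.96,0.96,0.97,0.97,0.98,0.98,0.98,0.99,0.99,1.00,0.97,0.98,1.00
Anhui,0.93,0.92,0.95,0.97,0.97,0.95,0.95,0.95,0.93,0.92,0.89,0.88,0.86
Fujian,0.95,0.95,0.95,0.94,0.94,0.93,0.93,0.93,0.92,0.92,0.92,0.92,0.91
Jiangxi,1.00,1.00,0.94,0.95,0.93,0.92,0.92,0.93,0.92,0.91,0.88,0.87,0.86
Shandong,0.79,0.81,1.00,1.00,0.92,0.82,0.83,0.83,0.80,0.73,0.64,0.66,0.68
Henan,0.81,0.81,0.87,0.83,0.87,0.86,0.87,0.90,0.85,0.83,0.71,0.68,0.63
Hubei,0.89,0.89,0.93,0.94,0.93,0.92,0.93,1.00,0.93,1.00,0.81,0.82,0.81
Hunan,0.79,0.80,0.82,0.85,0.82,0.81,0.83,0.82,1.00,1.00,0.77,0.77,0.79
Guangdong,0.97,0.95,0.97,1.00,1.00,0.99,1.00,1.00,0.99,1.00,0.83,0.83,0.81
Guangxi,0.97,0.93,0.96,1.00,0.95,0.93,0.92,0.90,0.89,0.90,0.86,0.85,0.84
Hainan,1.00,1.00,0.90,1.00,1.00,1.00,1.00,0.99,0.99,0.99,0.99,0.98,0.98
Chongqing,0.98,0.97,1.00,1.00,0.99,0.97,0.97,1.00,0.97,1.00,0.96,0.97,0.95
Sichuan,0.93,0.87,1.00,0.94,0.87,0.83,0.85,0.90,0.85,1.00,0.74,0.73,0.76
Guizhou,1.00,0.98,1.00,0.99,0.94,0.92,0.91,0.90,0.90,0.90,0.87,0.88,0.89
Yunnan,0.97,0.96,0.97,0.97,0.96,0.95,0.95,0.94,0.93,0.92,0.90,0.91,0.91
Shaanxi,0.90,0.89,0.89,0.90,0.90,0.89,0.89,0.89,0.88,0.87,0.86,0.86,0.86
Gansu,0.94,0.94,0.93,0.94,0.94,0.94,0.94,0.93,0.93,0.93,0.92,0.91,0.91
Qinghai,1.00,1.00,0.99,0.99,0.99,0.99,0.99,0.99,0.99,0.99,0.99,0.99,0.99
Ningxia,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,1.00,0.99,0.99,0.99
Xinjiang,0.97,0.96,0.96,0.96,0.96,0.96,0.96,0.95,0.94,0.94,0.93,0.92,0.93
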