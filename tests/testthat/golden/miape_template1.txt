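Instrument model	Q Exactive - Orbitrap_MS
Ion source spray voltage (kV)	2.1
Capillary temperature (C)	275
Polarity	positive
MS1 resolution	70000
MS1 AGC target	3000000
MS1 maximum injection time (ms)	20
Scan range (m/z)	300 to 1750
MS2 resolution	17500
Isolation window (m/z)	1.6
Normalized collision energy	27
Precursors per cycle (TopN)	10
Dynamic exclusion (s)	20
Acquisition software version	2.9.0.2926
LC instrument model	Thermo EASY-nLC
Mobile phase A	0.1% formic acid in water
Mobile phase B	0.1% formic acid in 80% acetonitrile
Column length (cm)	50
Column inner diameter (um)	75
Column oven temperature (C)	(not recorded)
Initial flow rate (nl/min)	300
Sample pickup volume (ul)	2
Column equilibration volume (ul)	4
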