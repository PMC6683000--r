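origin_key	instrument	term_label	source_path	display_order	required
miape	Q Exactive - Orbitrap_MS	Instrument model	Q Exactive - Orbitrap_MS/Instrument model	10	true
miape	Q Exactive - Orbitrap_MS	Ion source spray voltage (kV)	Tune/Spray voltage (kV)	20	true
miape	Q Exactive - Orbitrap_MS	Capillary temperature (C)	Tune/Capillary temperature (C)	30	false
miape	Q Exactive - Orbitrap_MS	Polarity	Method/Polarity	40	true
miape	Q Exactive - Orbitrap_MS	MS1 resolution	Full MS/Resolution	50	true
miape	Q Exactive - Orbitrap_MS	MS1 AGC target	Full MS/AGC target	60	false
miape	Q Exactive - Orbitrap_MS	MS1 maximum injection time (ms)	Full MS/Maximum injection time (ms)	70	false
miape	Q Exactive - Orbitrap_MS	Scan range (m/z)	Full MS/Scan range (m\/z)	80	true
miape	Q Exactive - Orbitrap_MS	MS2 resolution	dd-MS2/Resolution	90	false
miape	Q Exactive - Orbitrap_MS	Isolation window (m/z)	dd-MS2/Isolation window (m\/z)	100	true
miape	Q Exactive - Orbitrap_MS	Normalized collision energy	dd-MS2/Normalized collision energy	110	true
miape	Q Exactive - Orbitrap_MS	Precursors per cycle (TopN)	dd-MS2/TopN	120	false
miape	Q Exactive - Orbitrap_MS	Dynamic exclusion (s)	dd-MS2/Dynamic exclusion (s)	130	false
miape	Q Exactive - Orbitrap_MS	Acquisition software version	Software/Tune version	140	false
miape	Thermo EASY-nLC	LC instrument model	Thermo EASY-nLC/Instrument model	210	true
miape	Thermo EASY-nLC	Mobile phase A	Properties/Mobile phase A	220	true
miape	Thermo EASY-nLC	Mobile phase B	Properties/Mobile phase B	230	true
miape	Thermo EASY-nLC	Column length (cm)	Properties/Column length (cm)	240	false
miape	Thermo EASY-nLC	Column inner diameter (um)	Properties/Column inner diameter (um)	250	false
miape	Thermo EASY-nLC	Column oven temperature (C)	Properties/Column temperature (C)	260	true
miape	Thermo EASY-nLC	Initial flow rate (nl/min)	Gradient/00/Flow (nl\/min)	270	false
miape	Thermo EASY-nLC	Sample pickup volume (ul)	Sample pickup (µl)	280	false
miape	Thermo EASY-nLC	Column equilibration volume (ul)	Equilibration (µl)	290	false
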