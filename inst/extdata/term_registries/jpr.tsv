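origin_key	instrument	term_label	source_path	display_order	required
jpr	Q Exactive - Orbitrap_MS	Mass spectrometer	Q Exactive - Orbitrap_MS/Instrument model	10	true
jpr	Q Exactive - Orbitrap_MS	Polarity	Method/Polarity	20	true
jpr	Q Exactive - Orbitrap_MS	Survey scan resolution	Full MS/Resolution	30	true
jpr	Q Exactive - Orbitrap_MS	Survey scan range (m/z)	Full MS/Scan range (m\/z)	40	true
jpr	Q Exactive - Orbitrap_MS	Fragmentation collision energy	dd-MS2/Normalized collision energy	50	true
jpr	Q Exactive - Orbitrap_MS	MS2 isolation window (m/z)	dd-MS2/Isolation window (m\/z)	60	false
jpr	Q Exactive - Orbitrap_MS	Data-dependent TopN	dd-MS2/TopN	70	false
jpr	Thermo EASY-nLC	LC system	Thermo EASY-nLC/Instrument model	110	true
jpr	Thermo EASY-nLC	Mobile phases	Properties/Mobile phase A	120	true
jpr	Thermo EASY-nLC	Gradient initial %B	Gradient/00/Percent B	130	false
jpr	Thermo EASY-nLC	Flow rate (nl/min)	Gradient/00/Flow (nl\/min)	140	false
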