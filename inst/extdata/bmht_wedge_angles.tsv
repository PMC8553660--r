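# BMHT dinucleotide wedge angles (degrees). roll/tilt derived from the
# gel-mobility wedge magnitudes and directions of Bolshoy, McNamara,
# Harrington & Trifonov (PNAS 1991); twist from Kabsch, Sander & Trifonov.
# Complementary steps carry equal roll and opposite tilt by construction.
step	roll	tilt	twist
AA	-6.4713	-3.1563	35.62
AC	-0.8785	0.662	34.4
AG	8.3949	0.2932	27.7
AT	2.6	0	31.5
CA	1.5343	-3.1458	34.5
CC	1.1437	-1.7612	33.67
CG	6.7	0	29.8
CT	8.3949	-0.2932	27.7
GA	-2.65	4.5899	36.9
GC	-5	0	40
GG	1.1437	1.7612	33.67
GT	-0.8785	-0.662	34.4
TA	0.9	0	36
TC	-2.65	-4.5899	36.9
TG	1.5343	3.1458	34.5
TT	-6.4713	3.1563	35.62
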