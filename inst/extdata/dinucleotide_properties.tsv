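# Dinucleotide-step properties used by the sliding-window encoders.
# enthalpy and stability in kcal/mol-bp (nearest-neighbor melting values,
# SantaLucia-style scale); bendability in degrees (protein-induced bending
# propensity). Values transcribed as printed in the source parameter table,
# including its broken complement symmetries (e.g. stability CC vs GG);
# no symmetrization is applied.
step	enthalpy	stability	bendability
AA	-7.6	-1.00	3.07
AT	-7.2	-0.88	2.6
AC	-8.5	-1.45	2.97
AG	-8.2	-1.3	2.31
TT	-7.6	-1	3.07
TA	-7.2	-0.58	6.74
TC	-7.8	-1.28	2.51
TG	-8.4	-1.44	3.58
CC	-8	-1.28	2.16
CA	-8.5	-1.45	3.58
CT	-7.8	-1.28	2.31
CG	-10.6	-2.24	2.81
GG	-8	-1.84	2.16
GA	-8.2	-1.3	2.51
GT	-8.4	-1.44	2.97
GC	-10.6	-2.24	3.06
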