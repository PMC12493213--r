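# Nearest-neighbor stacking parameters, RNA/RNA homoduplex.
# provenance: Xia T, SantaLucia J Jr, Burkard ME, Kierzek R, Schroeder SJ,
#   Jiao X, Cox C, Turner DH (1998) Biochemistry 37:14719-14735
#   (Watson-Crick stacks). Values stored as negative quantities.
# units: dH_kcal in kcal/mol, dS_cal in cal/(mol K), per doublet step.
# key: doublet read 5'->3' on the target (RNA) strand; T denotes U.
#   16 keys expanded from the 10 unique stacks by symmetry.
doublet	dH_kcal	dS_cal
AA	-6.82	-19.0
AT	-9.38	-26.7
AG	-10.48	-27.1
AC	-11.40	-29.5
TA	-7.69	-20.5
TT	-6.82	-19.0
TG	-10.44	-26.9
TC	-12.44	-32.5
GA	-12.44	-32.5
GT	-11.40	-29.5
GG	-13.39	-32.7
GC	-14.88	-36.9
CA	-10.44	-26.9
CT	-10.48	-27.1
CG	-10.64	-26.7
CC	-13.39	-32.7
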