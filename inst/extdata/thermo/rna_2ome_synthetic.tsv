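# Nearest-neighbor stacking parameters, RNA / 2'-O-methyl-RNA heteroduplex.
# SYNTHETIC TABLE: per-doublet parameters for this chemistry were not
# available for transcription; this table is constructed from the Xia et
# al. (1998) RNA/RNA stacks with a -0.40 kcal/mol enthalpy bonus per step
# (entropy unchanged), i.e. a net stabilization of ~0.4 kcal/mol free
# energy per 2'-O-methyl step, consistent with the per-residue increments
# of Freier SM, Altmann KH (1997) Nucleic Acids Res 25:4429-4443. Replace
# with measured parameters when transcribing from a primary source.
# units: dH_kcal in kcal/mol, dS_cal in cal/(mol K), per doublet step.
# key: doublet read 5'->3' on the unmodified target RNA strand; T denotes U.
doublet	dH_kcal	dS_cal
AA	-7.22	-19.0
AT	-9.78	-26.7
AG	-10.88	-27.1
AC	-11.80	-29.5
TA	-8.09	-20.5
TT	-7.22	-19.0
TG	-10.84	-26.9
TC	-12.84	-32.5
GA	-12.84	-32.5
GT	-11.80	-29.5
GG	-13.79	-32.7
GC	-15.28	-36.9
CA	-10.84	-26.9
CT	-10.88	-27.1
CG	-11.04	-26.7
CC	-13.79	-32.7
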