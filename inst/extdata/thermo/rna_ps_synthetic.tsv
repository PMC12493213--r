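# Nearest-neighbor stacking parameters, RNA / phosphorothioate-RNA
# heteroduplex. SYNTHETIC TABLE: per-doublet parameters for this chemistry
# were not available for transcription; this table is constructed from the
# Xia et al. (1998) RNA/RNA stacks with a +0.30 kcal/mol enthalpy penalty
# per step (entropy unchanged), i.e. a net destabilization of ~0.3 kcal/mol
# free energy per phosphorothioate linkage, consistent with the commonly
# reported ~0.5 C Tm loss per PS substitution. Replace with measured
# parameters when transcribing from a primary source.
# units: dH_kcal in kcal/mol, dS_cal in cal/(mol K), per doublet step.
# key: doublet read 5'->3' on the unmodified target RNA strand; T denotes U.
doublet	dH_kcal	dS_cal
AA	-6.52	-19.0
AT	-9.08	-26.7
AG	-10.18	-27.1
AC	-11.10	-29.5
TA	-7.39	-20.5
TT	-6.52	-19.0
TG	-10.14	-26.9
TC	-12.14	-32.5
GA	-12.14	-32.5
GT	-11.10	-29.5
GG	-13.09	-32.7
GC	-14.58	-36.9
CA	-10.14	-26.9
CT	-10.18	-27.1
CG	-10.34	-26.7
CC	-13.09	-32.7
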