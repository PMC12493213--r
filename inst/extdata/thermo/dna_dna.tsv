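# Nearest-neighbor stacking parameters, DNA/DNA homoduplex.
# provenance: Breslauer KJ, Frank R, Bloecker H, Marky LA (1986)
#   Proc Natl Acad Sci USA 83:3746-3750; parameter set used by the
#   OligoCalc nearest-neighbor method (Kibbe WA (2007) Nucleic Acids Res
#   35:W43-W46). Values stored as negative (stabilizing) quantities.
# units: dH_kcal in kcal/mol, dS_cal in cal/(mol K), per doublet step.
# key: doublet read 5'->3' on the target (sense) strand; the 16 keys are
#   expanded from the 10 unique stacks by reverse-complement symmetry.
doublet	dH_kcal	dS_cal
AA	-9.1	-24.0
AT	-8.6	-23.9
AG	-7.8	-20.8
AC	-6.5	-17.3
TA	-6.0	-16.9
TT	-9.1	-24.0
TG	-5.8	-12.9
TC	-5.6	-13.5
GA	-5.6	-13.5
GT	-6.5	-17.3
GG	-11.0	-26.6
GC	-11.1	-26.7
CA	-5.8	-12.9
CT	-7.8	-20.8
CG	-11.9	-27.8
CC	-11.0	-26.6
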