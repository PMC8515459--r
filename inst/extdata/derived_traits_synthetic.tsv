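# Synthetic stand-in for the 45 derived glycosylation traits (the original
# trait formula table is not publicly available). Scope and feature use the
# selector language documented in ?read_trait_panel. Weightings:
#   fraction      sum(ab | scope & feature) / sum(ab | scope)
#   per-antenna   sum(count * ab | scope) / sum(antennarity * ab | scope)
#   per-galactose sum(count * ab | scope) / sum(galactoses * ab | scope)
#   ratio         sum(ab | feature) / sum(ab | scope)
name	scope	feature	weighting	description
MHy	hybrid	highman	ratio	Ratio of high-mannose to hybrid glycans.
TM	all	highman	fraction	High-mannose glycans within total.
THy	all	hybrid	fraction	Hybrid glycans within total.
TC	all	complex	fraction	Complex-type glycans within total.
CA1	complex	A1	fraction	Relative abundance of A1 glycans within complex-type glycans.
CA2	complex	A2	fraction	Relative abundance of A2 glycans within complex-type glycans.
CA3	complex	A3	fraction	Relative abundance of A3 glycans within complex-type glycans.
CA4	complex	A4	fraction	Relative abundance of A4 glycans within complex-type glycans.
CF	complex	F	fraction	Fucosylation of complex-type glycans.
A1F	complex&A1	F	fraction	Fucosylation in A1 glycans.
A2F	complex&A2	F	fraction	Fucosylation in A2 glycans.
A3F	complex&A3	F	fraction	Fucosylation in A3 glycans.
A4F	complex&A4	F	fraction	Fucosylation in A4 glycans.
A2E0F	complex&A2&E0	F	fraction	Fucosylation in A2 glycans without alpha2,6-linked sialic acid.
A2L0F	complex&A2&L0	F	fraction	Fucosylation in A2 glycans without alpha2,3-linked sialic acid.
A2S0F	complex&A2&S0	F	fraction	Fucosylation in non-sialylated A2.
A2B	complex&A2	B	fraction	Bisection in A2 glycans.
A2FS0B	complex&A2&F&S0	B	fraction	Bisection in fucosylated non-sialylated A2.
A2F0S0B	complex&A2&F0&S0	B	fraction	Bisection in non-fucosylated non-sialylated A2.
A2G	complex&A2	G	per-antenna	Galactosylation per antenna in A2.
A2FG	complex&A2&F	G	per-antenna	Galactosylation per antenna in fucosylated A2.
A2F0G	complex&A2&F0	G	per-antenna	Galactosylation per antenna in non-fucosylated A2.
A2FS0G	complex&A2&F&S0	G	per-antenna	Galactosylation per antenna in fucosylated non-sialylated A2.
A2F0S0G	complex&A2&F0&S0	G	per-antenna	Galactosylation per antenna in non-fucosylated non-sialylated A2.
A2S	complex&A2	S	per-antenna	Sialylation per antenna in A2.
A3S	complex&A3	S	per-antenna	Sialylation per antenna in A3.
A4S	complex&A4	S	per-antenna	Sialylation per antenna in A4.
A2FGS	complex&A2&F	S	per-galactose	Sialylation per galactose in fucosylated A2.
A2F0GS	complex&A2&F0	S	per-galactose	Sialylation per galactose in non-fucosylated A2.
A4FGS	complex&A4&F	S	per-galactose	Sialylation per galactose in fucosylated A4.
A4F0GS	complex&A4&F0	S	per-galactose	Sialylation per galactose in non-fucosylated A4.
A2L	complex&A2	L	per-antenna	Alpha2,3-sialylation per antenna in A2.
A3L	complex&A3	L	per-antenna	Alpha2,3-sialylation per antenna in A3.
A4L	complex&A4	L	per-antenna	Alpha2,3-sialylation per antenna in A4.
A2FGL	complex&A2&F	L	per-galactose	Alpha2,3-sialylation per galactose in fucosylated A2.
A2F0GL	complex&A2&F0	L	per-galactose	Alpha2,3-sialylation per galactose in non-fucosylated A2.
A4FGL	complex&A4&F	L	per-galactose	Alpha2,3-sialylation per galactose in fucosylated A4.
A4F0GL	complex&A4&F0	L	per-galactose	Alpha2,3-sialylation per galactose in non-fucosylated A4.
A2E	complex&A2	E	per-antenna	Alpha2,6-sialylation per antenna in A2.
A3E	complex&A3	E	per-antenna	Alpha2,6-sialylation per antenna in A3.
A4E	complex&A4	E	per-antenna	Alpha2,6-sialylation per antenna in A4.
A2FGE	complex&A2&F	E	per-galactose	Alpha2,6-sialylation per galactose in fucosylated A2.
A2F0GE	complex&A2&F0	E	per-galactose	Alpha2,6-sialylation per galactose in non-fucosylated A2.
A4FGE	complex&A4&F	E	per-galactose	Alpha2,6-sialylation per galactose in fucosylated A4.
A4F0GE	complex&A4&F0	E	per-galactose	Alpha2,6-sialylation per galactose in non-fucosylated A4.
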