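# Carbohydrate HET-code lexicon (editable).
# One 3-letter chemical component code per line; '#' starts a comment.
# This shipped list is a synthetic stand-in covering common mono- and
# oligosaccharide components seen in carbohydrate-protein complexes; edit or
# replace it to match your own curation.  Water (HOH) is always refused even
# if listed here.
GLC
BGC
GAL
GLA
MAN
BMA
FUC
FUL
XYS
XYP
ARA
ARB
RIB
RIP
FRU
SIA
NAG
NDG
NGA
A2G
GCU
BDP
IDR
GCS
GLP
G6P
F6P
M6P
BGL
MAL
LAT
LBT
SUC
TRE
CBI
CTT
KDO
GMH
RAM
AHR
ABE
TYV
PAR
DHA
GUP
ALL
AFD
SHG
Z9N
MGC
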