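ADM
AK4
ALDOA
ANGPTL4
ANKRD37
BHLHE40
BNIP3L
C4orf3
C8orf58
CTDSP1
DDIT4
DENND1A
EGLN1
ENO1
ESYT2
FUT11
GBE1
GPI
HERC3
HK2
KCTD11
KDM3A
KDM4B
KDM4C
LDHA
LONP1
MIR210HG
MXI1
NCKIPSD
NDRG1
NPEPPS
P4HA1
PDLIM2
PFKFB4
PGAM1
PGK1
PKM
PLOD2
PNRC1
RBPJ
SAP30
SCD
SEMA4B
SLC16A3
SLC2A1
STC2
TNIP1
ZNF395
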