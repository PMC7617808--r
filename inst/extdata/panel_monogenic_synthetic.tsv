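ACP5
C3
C4A
C4B
DNASE1
DNASE1L3
IFIH1
NRAS
RNASEH2A
RNASEH2B
RNASEH2C
SAMHD1
TREX1
ADA2
TLR7
UNC93B1
SAT1
TNIP1
PACSIN1
SH2B3
P2RY8
DDX58
NLRC4
DOCK8
FAS
FASLG
LRBA
CYBB
MAN2B1
SLC7A7
TMEM173
C1QA
C1QB
C1QC
C1R
C1S
C2
PRKCD
PTEN
KRAS
STAT1
STAT3
ISG15
POLB
PEPD
SHOC2
RRAGD
TNFAIP3
SOCS1
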