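TYK2
C4A
C4B
BLK
LYST
UHRF1BP1
IKBKE
STAT4
IRF5
IRF7
IRF8
BANK1
ITGAM
TNFSF4
PTPN22
ETS1
IKZF1
TNFAIP3
TNIP1
SLC15A4
WDFY4
ATG5
PRDM1
LYN
NCF2
CSK
FCGR2A
FCGR2B
IL10
IL12A
UBE2L3
PHRF1
GADD45A
TET2
SLEG001
SLEG002
SLEG003
SLEG004
SLEG005
SLEG006
SLEG007
SLEG008
SLEG009
SLEG010
SLEG011
SLEG012
SLEG013
SLEG014
SLEG015
SLEG016
SLEG017
SLEG018
SLEG019
SLEG020
SLEG021
SLEG022
SLEG023
SLEG024
SLEG025
SLEG026
SLEG027
SLEG028
SLEG029
SLEG030
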