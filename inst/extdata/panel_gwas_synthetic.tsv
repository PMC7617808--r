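STAT4
IRF5
IRF7
IRF8
TNFAIP3
TNIP1
BLK
BANK1
TYK2
ITGAM
TNFSF4
PTPN22
ETS1
IKZF1
IKZF2
IKZF3
TNFSF13B
CD44
FCGR2A
FCGR2B
IL10
IL12A
JAZF1
UBE2L3
WDFY4
TNXB
ATG5
PRDM1
PXK
RASGRP3
SLC15A4
LYN
NCF2
CSK
CIITA
SPRED2
PHRF1
UHRF1BP1
IKBKE
LYST
GADD45A
TET2
C4A
C4B
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
SLEG031
SLEG032
SLEG033
SLEG034
SLEG035
SLEG036
SLEG037
SLEG038
SLEG039
SLEG040
SLEG041
SLEG042
SLEG043
SLEG044
SLEG045
SLEG046
SLEG047
SLEG048
SLEG049
SLEG050
SLEG051
SLEG052
SLEG053
SLEG054
SLEG055
SLEG056
SLEG057
SLEG058
SLEG059
SLEG060
SLEG061
SLEG062
SLEG063
SLEG064
SLEG065
SLEG066
SLEG067
SLEG068
SLEG069
SLEG070
SLEG071
SLEG072
SLEG073
SLEG074
SLEG075
SLEG076
SLEG077
SLEG078
SLEG079
SLEG080
SLEG081
SLEG082
SLEG083
SLEG084
SLEG085
SLEG086
SLEG087
SLEG088
SLEG089
SLEG090
SLEG091
SLEG092
SLEG093
SLEG094
SLEG095
SLEG096
SLEG097
SLEG098
SLEG099
SLEG100
SLEG101
SLEG102
SLEG103
SLEG104
SLEG105
SLEG106
SLEG107
SLEG108
SLEG109
SLEG110
SLEG111
SLEG112
SLEG113
SLEG114
SLEG115
SLEG116
SLEG117
SLEG118
SLEG119
SLEG120
SLEG121
SLEG122
SLEG123
SLEG124
SLEG125
SLEG126
SLEG127
SLEG128
SLEG129
SLEG130
SLEG131
SLEG132
SLEG133
SLEG134
SLEG135
SLEG136
SLEG137
SLEG138
SLEG139
SLEG140
SLEG141
SLEG142
SLEG143
SLEG144
SLEG145
SLEG146
SLEG147
SLEG148
SLEG149
SLEG150
SLEG151
SLEG152
SLEG153
SLEG154
SLEG155
SLEG156
SLEG157
SLEG158
SLEG159
SLEG160
SLEG161
SLEG162
SLEG163
SLEG164
SLEG165
SLEG166
SLEG167
SLEG168
SLEG169
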