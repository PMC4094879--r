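# Synthetic stand-in seed list: 77 unique gene identifiers, one per
# line, mirroring the shape of a curated disease-gene list.
SYNSEED001
SYNSEED002
SYNSEED003
SYNSEED004
SYNSEED005
SYNSEED006
SYNSEED007
SYNSEED008
SYNSEED009
SYNSEED010
SYNSEED011
SYNSEED012
SYNSEED013
SYNSEED014
SYNSEED015
SYNSEED016
SYNSEED017
SYNSEED018
SYNSEED019
SYNSEED020
SYNSEED021
SYNSEED022
SYNSEED023
SYNSEED024
SYNSEED025
SYNSEED026
SYNSEED027
SYNSEED028
SYNSEED029
SYNSEED030
SYNSEED031
SYNSEED032
SYNSEED033
SYNSEED034
SYNSEED035
SYNSEED036
SYNSEED037
SYNSEED038
SYNSEED039
SYNSEED040
SYNSEED003
SYNSEED041
SYNSEED042
SYNSEED043
SYNSEED044
SYNSEED045
SYNSEED046
SYNSEED047
SYNSEED048
SYNSEED049
SYNSEED050
SYNSEED051
SYNSEED052
SYNSEED053
SYNSEED054
SYNSEED055
SYNSEED056
SYNSEED057
SYNSEED058
SYNSEED059
SYNSEED060
SYNSEED061
SYNSEED062
SYNSEED063
SYNSEED064
SYNSEED065
SYNSEED066
SYNSEED067
SYNSEED068
SYNSEED069
SYNSEED070
SYNSEED071
SYNSEED072
SYNSEED073
SYNSEED074
SYNSEED075
SYNSEED076
SYNSEED077
SYNSEED010 # trailing comment
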