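# theoretical structure: 8 reciprocal cross-region dealer pairs
# traders T01-T08 belong to region 1, T09-T16 to region 2
nodes: T01:dealer,T02:dealer,T03:dealer,T04:dealer,T05:dealer,T06:dealer,T07:dealer,T08:dealer,T09:dealer,T10:dealer,T11:dealer,T12:dealer,T13:dealer,T14:dealer,T15:dealer,T16:dealer
T01 T09
T02 T10
T03 T11
T04 T12
T05 T13
T06 T14
T07 T15
T08 T16
T09 T01
T10 T02
T11 T03
T12 T04
T13 T05
T14 T06
T15 T07
T16 T08
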