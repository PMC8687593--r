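# theoretical structure: fully connected, 240 directed edges
nodes: T01:dealer,T02:dealer,T03:dealer,T04:dealer,T05:dealer,T06:dealer,T07:dealer,T08:dealer,T09:dealer,T10:dealer,T11:dealer,T12:dealer,T13:dealer,T14:dealer,T15:dealer,T16:dealer
T01 T02
T01 T03
T01 T04
T01 T05
T01 T06
T01 T07
T01 T08
T01 T09
T01 T10
T01 T11
T01 T12
T01 T13
T01 T14
T01 T15
T01 T16
T02 T01
T02 T03
T02 T04
T02 T05
T02 T06
T02 T07
T02 T08
T02 T09
T02 T10
T02 T11
T02 T12
T02 T13
T02 T14
T02 T15
T02 T16
T03 T01
T03 T02
T03 T04
T03 T05
T03 T06
T03 T07
T03 T08
T03 T09
T03 T10
T03 T11
T03 T12
T03 T13
T03 T14
T03 T15
T03 T16
T04 T01
T04 T02
T04 T03
T04 T05
T04 T06
T04 T07
T04 T08
T04 T09
T04 T10
T04 T11
T04 T12
T04 T13
T04 T14
T04 T15
T04 T16
T05 T01
T05 T02
T05 T03
T05 T04
T05 T06
T05 T07
T05 T08
T05 T09
T05 T10
T05 T11
T05 T12
T05 T13
T05 T14
T05 T15
T05 T16
T06 T01
T06 T02
T06 T03
T06 T04
T06 T05
T06 T07
T06 T08
T06 T09
T06 T10
T06 T11
T06 T12
T06 T13
T06 T14
T06 T15
T06 T16
T07 T01
T07 T02
T07 T03
T07 T04
T07 T05
T07 T06
T07 T08
T07 T09
T07 T10
T07 T11
T07 T12
T07 T13
T07 T14
T07 T15
T07 T16
T08 T01
T08 T02
T08 T03
T08 T04
T08 T05
T08 T06
T08 T07
T08 T09
T08 T10
T08 T11
T08 T12
T08 T13
T08 T14
T08 T15
T08 T16
T09 T01
T09 T02
T09 T03
T09 T04
T09 T05
T09 T06
T09 T07
T09 T08
T09 T10
T09 T11
T09 T12
T09 T13
T09 T14
T09 T15
T09 T16
T10 T01
T10 T02
T10 T03
T10 T04
T10 T05
T10 T06
T10 T07
T10 T08
T10 T09
T10 T11
T10 T12
T10 T13
T10 T14
T10 T15
T10 T16
T11 T01
T11 T02
T11 T03
T11 T04
T11 T05
T11 T06
T11 T07
T11 T08
T11 T09
T11 T10
T11 T12
T11 T13
T11 T14
T11 T15
T11 T16
T12 T01
T12 T02
T12 T03
T12 T04
T12 T05
T12 T06
T12 T07
T12 T08
T12 T09
T12 T10
T12 T11
T12 T13
T12 T14
T12 T15
T12 T16
T13 T01
T13 T02
T13 T03
T13 T04
T13 T05
T13 T06
T13 T07
T13 T08
T13 T09
T13 T10
T13 T11
T13 T12
T13 T14
T13 T15
T13 T16
T14 T01
T14 T02
T14 T03
T14 T04
T14 T05
T14 T06
T14 T07
T14 T08
T14 T09
T14 T10
T14 T11
T14 T12
T14 T13
T14 T15
T14 T16
T15 T01
T15 T02
T15 T03
T15 T04
T15 T05
T15 T06
T15 T07
T15 T08
T15 T09
T15 T10
T15 T11
T15 T12
T15 T13
T15 T14
T15 T16
T16 T01
T16 T02
T16 T03
T16 T04
T16 T05
T16 T06
T16 T07
T16 T08
T16 T09
T16 T10
T16 T11
T16 T12
T16 T13
T16 T14
T16 T15
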