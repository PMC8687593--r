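# synthetic stand-in for the same-density network with more dealers
# motif-biased generator: n=16, 21 edges, 12 dealers / 4 sellers,
# reciprocity_weight=6, centralization_weight=0.3, seed=72
nodes: T01:dealer,T02:seller,T03:dealer,T04:dealer,T05:dealer,T06:seller,T07:dealer,T08:seller,T09:seller,T10:dealer,T11:dealer,T12:dealer,T13:dealer,T14:dealer,T15:dealer,T16:dealer
T01 T11
T03 T05
T03 T13
T04 T02
T05 T03
T05 T15
T07 T01
T07 T14
T10 T16
T11 T01
T11 T02
T11 T15
T12 T04
T13 T07
T13 T10
T14 T07
T15 T05
T15 T09
T15 T16
T16 T08
T16 T15
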