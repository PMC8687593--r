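# synthetic stand-in for an empirically informed mixed network
# motif-biased generator: n=16, 21 edges, 6 dealers / 10 sellers,
# reciprocity_weight=6, centralization_weight=0.3, seed=1
nodes: T01:dealer,T02:dealer,T03:seller,T04:dealer,T05:seller,T06:seller,T07:dealer,T08:seller,T09:dealer,T10:seller,T11:seller,T12:seller,T13:seller,T14:dealer,T15:seller,T16:seller
T01 T03
T01 T04
T01 T08
T01 T09
T01 T11
T01 T12
T02 T04
T02 T12
T02 T16
T04 T01
T04 T02
T04 T06
T04 T07
T04 T08
T04 T12
T07 T04
T07 T10
T07 T13
T09 T01
T14 T02
T14 T10
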