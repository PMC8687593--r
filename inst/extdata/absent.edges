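# theoretical structure: 16 isolated sellers (absence of network)
nodes: T01:seller,T02:seller,T03:seller,T04:seller,T05:seller,T06:seller,T07:seller,T08:seller,T09:seller,T10:seller,T11:seller,T12:seller,T13:seller,T14:seller,T15:seller,T16:seller
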