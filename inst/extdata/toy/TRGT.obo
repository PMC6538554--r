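format-version: 1.2

[Term]
id: TRGT:0000000
name: TRGT term 0

[Term]
id: TRGT:0000001
name: TRGT term 1
is_a: TRGT:0000000

[Term]
id: TRGT:0000002
name: TRGT term 2
is_a: TRGT:0000000

[Term]
id: TRGT:0000003
name: TRGT term 3
is_a: TRGT:0000000

[Term]
id: TRGT:0000004
name: TRGT term 4
is_a: TRGT:0000002

[Term]
id: TRGT:0000005
name: TRGT term 5
is_a: TRGT:0000001

[Term]
id: TRGT:0000006
name: TRGT term 6
is_a: TRGT:0000003

[Term]
id: TRGT:0000007
name: TRGT term 7
is_a: TRGT:0000001

[Term]
id: TRGT:0000008
name: TRGT term 8
is_a: TRGT:0000001
is_a: TRGT:0000005

[Term]
id: TRGT:0000009
name: TRGT term 9
is_a: TRGT:0000005

[Term]
id: TRGT:0000010
name: TRGT term 10
is_a: TRGT:0000005

[Term]
id: TRGT:0000011
name: TRGT term 11
is_a: TRGT:0000002
is_a: TRGT:0000004

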