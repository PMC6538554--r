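format-version: 1.2

[Term]
id: SRCB:0000000
name: SRCB term 0

[Term]
id: SRCB:0000001
name: SRCB term 1
is_a: SRCB:0000000

[Term]
id: SRCB:0000002
name: SRCB term 2
is_a: SRCB:0000000

[Term]
id: SRCB:0000003
name: SRCB term 3
is_a: SRCB:0000000

[Term]
id: SRCB:0000004
name: SRCB term 4
is_a: SRCB:0000003

[Term]
id: SRCB:0000005
name: SRCB term 5
is_a: SRCB:0000003

[Term]
id: SRCB:0000006
name: SRCB term 6
is_a: SRCB:0000003
is_a: SRCB:0000004

[Term]
id: SRCB:0000007
name: SRCB term 7
is_a: SRCB:0000001

[Term]
id: SRCB:0000008
name: SRCB term 8
is_a: SRCB:0000002

[Term]
id: SRCB:0000009
name: SRCB term 9
is_a: SRCB:0000007

[Term]
id: SRCB:0000010
name: SRCB term 10
is_a: SRCB:0000002
is_a: SRCB:0000008

[Term]
id: SRCB:0000011
name: SRCB term 11
is_a: SRCB:0000002

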