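format-version: 1.2

[Term]
id: NOIS:0000000
name: NOIS term 0

[Term]
id: NOIS:0000001
name: NOIS term 1
is_a: NOIS:0000000

[Term]
id: NOIS:0000002
name: NOIS term 2
is_a: NOIS:0000000

[Term]
id: NOIS:0000003
name: NOIS term 3
is_a: NOIS:0000000

[Term]
id: NOIS:0000004
name: NOIS term 4
is_a: NOIS:0000001

[Term]
id: NOIS:0000005
name: NOIS term 5
is_a: NOIS:0000001
is_a: NOIS:0000004

[Term]
id: NOIS:0000006
name: NOIS term 6
is_a: NOIS:0000002

[Term]
id: NOIS:0000007
name: NOIS term 7
is_a: NOIS:0000003

[Term]
id: NOIS:0000008
name: NOIS term 8
is_a: NOIS:0000001
is_a: NOIS:0000004

[Term]
id: NOIS:0000009
name: NOIS term 9
is_a: NOIS:0000003

[Term]
id: NOIS:0000010
name: NOIS term 10
is_a: NOIS:0000004
is_a: NOIS:0000005

[Term]
id: NOIS:0000011
name: NOIS term 11
is_a: NOIS:0000008

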