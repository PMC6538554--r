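format-version: 1.2

[Term]
id: SRCA:0000000
name: SRCA term 0

[Term]
id: SRCA:0000001
name: SRCA term 1
is_a: SRCA:0000000

[Term]
id: SRCA:0000002
name: SRCA term 2
is_a: SRCA:0000000

[Term]
id: SRCA:0000003
name: SRCA term 3
is_a: SRCA:0000000

[Term]
id: SRCA:0000004
name: SRCA term 4
is_a: SRCA:0000001

[Term]
id: SRCA:0000005
name: SRCA term 5
is_a: SRCA:0000002

[Term]
id: SRCA:0000006
name: SRCA term 6
is_a: SRCA:0000003

[Term]
id: SRCA:0000007
name: SRCA term 7
is_a: SRCA:0000002

[Term]
id: SRCA:0000008
name: SRCA term 8
is_a: SRCA:0000006

[Term]
id: SRCA:0000009
name: SRCA term 9
is_a: SRCA:0000007

[Term]
id: SRCA:0000010
name: SRCA term 10
is_a: SRCA:0000001

[Term]
id: SRCA:0000011
name: SRCA term 11
is_a: SRCA:0000006
is_a: SRCA:0000008

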