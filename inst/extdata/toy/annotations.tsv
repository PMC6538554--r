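res0001	SRCA:0000003
res0001	SRCA:0000006
res0001	SRCA:0000011
res0001	TRGT:0000003
res0002	SRCA:0000005
res0002	SRCA:0000007
res0002	TRGT:0000007
res0003	NOIS:0000005
res0003	NOIS:0000006
res0003	SRCA:0000002
res0003	SRCA:0000007
res0003	SRCA:0000009
res0003	TRGT:0000007
res0004	SRCA:0000002
res0004	SRCA:0000007
res0004	SRCB:0000002
res0004	SRCB:0000011
res0004	TRGT:0000007
res0005	NOIS:0000003
res0005	NOIS:0000004
res0005	NOIS:0000009
res0005	SRCB:0000003
res0005	SRCB:0000004
res0005	SRCB:0000005
res0005	SRCB:0000006
res0005	TRGT:0000003
res0006	SRCA:0000001
res0006	SRCA:0000004
res0006	SRCA:0000010
res0006	TRGT:0000010
res0007	NOIS:0000004
res0007	SRCA:0000011
res0007	SRCB:0000003
res0007	TRGT:0000003
res0008	NOIS:0000002
res0008	NOIS:0000005
res0008	NOIS:0000008
res0008	SRCA:0000005
res0008	SRCB:0000010
res0008	TRGT:0000007
res0009	NOIS:0000004
res0009	NOIS:0000008
res0009	SRCA:0000002
res0009	SRCA:0000005
res0009	SRCA:0000007
res0009	SRCA:0000009
res0009	TRGT:0000007
res0010	SRCB:0000011
res0010	TRGT:0000007
res0011	SRCB:0000003
res0011	SRCB:0000004
res0011	TRGT:0000003
res0012	NOIS:0000002
res0012	NOIS:0000008
res0012	SRCA:0000002
res0012	SRCA:0000005
res0012	SRCA:0000007
res0012	SRCA:0000009
res0012	TRGT:0000007
res0013	NOIS:0000001
res0013	NOIS:0000003
res0013	SRCB:0000001
res0013	SRCB:0000007
res0013	SRCB:0000009
res0013	TRGT:0000010
res0014	SRCA:0000008
res0014	TRGT:0000003
res0015	SRCB:0000003
res0015	SRCB:0000004
res0015	SRCB:0000005
res0015	SRCB:0000006
res0015	TRGT:0000003
res0016	NOIS:0000006
res0016	SRCA:0000003
res0016	SRCA:0000008
res0016	SRCB:0000004
res0016	TRGT:0000003
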