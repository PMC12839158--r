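name	lipid_class	molecular_weight	loq
C12:0	SFA	200.32	NA
C14:0	SFA	228.37	NA
C16:0	SFA	256.42	NA
C17:0	SFA	270.45	NA
C18:0	SFA	284.48	NA
C20:0	SFA	312.53	NA
C22:0	SFA	340.58	NA
C24:0	SFA	368.63	NA
C16:1n-7	MUFA	254.41	NA
C18:1n-9	MUFA	282.46	NA
C20:1n-9	MUFA	310.51	NA
C24:1n-9	MUFA	366.62	NA
C16:1n-7t	TRANS	254.41	NA
C18:1n-9t	TRANS	282.46	NA
C18:2n-6t	TRANS	280.45	NA
C18:2n-6	PUFA-n6	280.45	NA
C18:3n-6	PUFA-n6	278.43	NA
C20:2n-6	PUFA-n6	308.5	NA
C20:3n-6	PUFA-n6	306.48	NA
C20:4n-6	PUFA-n6	304.47	NA
C22:4n-6	PUFA-n6	332.52	NA
C20:5n-3	PUFA-n3	302.45	NA
C22:5n-3	PUFA-n3	330.5	NA
C22:6n-3	PUFA-n3	328.49	NA
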