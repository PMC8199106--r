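gene_id	origin	donor_id
gene_0001	Bacteria	Bacteria_004
gene_0002	Bacteria	Bacteria_004
gene_0003	Bacteria	Bacteria_003
gene_0004	Bacteria	Bacteria_006
gene_0005	Bacteria	Bacteria_006
gene_0006	Bacteria	Bacteria_001
gene_0007	Bacteria	Bacteria_003
gene_0008	Bacteria	Bacteria_005
gene_0009	Bacteria	Bacteria_002
gene_0010	Bacteria	Bacteria_004
gene_0011	Bacteria	Bacteria_006
gene_0012	Bacteria	Bacteria_005
gene_0013	Bacteria	Bacteria_005
gene_0014	Bacteria	Bacteria_006
gene_0015	Bacteria	Bacteria_001
gene_0016	CPR	CPR_005
gene_0017	CPR	CPR_002
gene_0018	CPR	CPR_002
gene_0019	CPR	CPR_002
gene_0020	CPR	CPR_001
gene_0021	CPR	CPR_002
gene_0022	CPR	CPR_003
gene_0023	CPR	CPR_002
gene_0024	CPR	CPR_006
gene_0025	ORFan	NA
gene_0026	ORFan	NA
gene_0027	ORFan	NA
gene_0028	ORFan	NA
gene_0029	Archaea	Archaea_005
gene_0030	Archaea	Archaea_002
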