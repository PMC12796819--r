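R-HSA-77111	Synthesis of ketone bodies (synthetic placeholder gene list)	HMGCS2	HMGCL	BDH1	ACAT1	OXCT1	HMGCLL1	BDH2	SLC16A6
R-HSA-191273	Cholesterol biosynthesis (synthetic placeholder gene list)	HMGCS1	HMGCR	MVK	PMVK	MVD	IDI1	FDPS	FDFT1	SQLE	LSS	CYP51A1	DHCR7	DHCR24	SC5D	MSMO1	NSDHL	HSD17B7	EBP	TM7SF2	LBR	ARV1	PLPP6	GGPS1	IDI2	FAXDC2
R-HSA-77289	Mitochondrial fatty acid beta-oxidation (synthetic placeholder gene list)	ACADM	ACADVL	ACADL	ACADS	ECI1	HADHA	HADHB	HADH	ACAA2	CPT1A	CPT2	SLC25A20	ETFA	ETFB	ACAD11
R-HSA-390918	Peroxisomal lipid metabolism (synthetic placeholder gene list)	ACOX1	ACOX2	ACOX3	EHHADH	HSD17B4	ACAA1	SCP2	AMACR	CROT	ABCD1	ABCD2	ABCD3	PHYH	HACL1
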