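pair_id	sanger_confirmed	immediate_neighbor	interstitial_deletion	ctcf_binding	sictcf_induced	intergenic_transcript	starred
SLC39A1-CRTC2	Y	Y	N	Y	N		FALSE
SMG5-PAQR6	Y	Y	N	Y	N		FALSE
METTL10-FAM53B	Y	Y	N	Y	N		FALSE
TFDP1-GRK1	Y	N	N	Y	Y		FALSE
ZNF592-ALPK3	Y	Y	N	Y	Y	Y	TRUE
MFGE8-HAPLN3	Y	Y	N	Y	Y	Y	TRUE
KIAA0753-PITPNM3	Y	Y	N	Y	N		FALSE
CIRBP-C19orf24	Y	Y	N	Y	N		FALSE
PROM2-KCNIP3	Y	Y	N	Y	Y	Y	TRUE
TP53RK-SLC13A3	N						FALSE
LINC00680-GUSBP4	Y	N	N	Y	Y		FALSE
TMED4-DDX56	Y	Y	N	Y	Y	Y	TRUE
PPP1R16A-GPT	Y	Y	N	Y	N		FALSE
TTTY15-USP9Y	Y	Y	N	Y	N		FALSE
ADCK4-Numbl	Y	Y	N	Y	Y	Y	TRUE
ADSL-SGSM3	Y	Y	N	Y	N		FALSE
AKAP8L-AKAP8	Y	Y	N	Y	N		FALSE
AP5S1-MAVS	Y	Y	N	Y	Y	Y	TRUE
BAIAP2L2-SLC16A8	Y	Y	N	Y	Y	Y	TRUE
C14orf80-TMEM121	Y	Y	N	Y	Y	Y	TRUE
CHCHD10-VPREB3F	Y	N	N	N	N		FALSE
CLN6-CALML4	Y	Y	N	Y	Y	Y	TRUE
CTNNBIP1-CLSTN1	Y	Y	N	Y	Y	Y	TRUE
D2HGDH-GAL3ST2	Y	Y	N	Y	Y	Y	TRUE
DMC1-DDX17	Y	Y	N	Y	N		FALSE
DMKN-KRTDAP	Y	Y	N	Y	N		FALSE
DPM2-PIP5KL1	Y	Y	N	Y	N		FALSE
EIF3K-ACTN4	Y	Y	N	N	N		FALSE
HDAC8-CITED1	Y	Y	N	Y	N		FALSE
MED12-NLGN3	Y	Y	N	Y	N		FALSE
NUDT14-JAG2	Y	Y	N	Y	Y	Y	TRUE
PRIM1-NACA	Y	Y	N	Y	Y	Y	TRUE
RRM2-C2orf48	Y	Y	N	Y	N		FALSE
SCNN1A-TNFRSF1A	Y	Y	N	Y	Y	Y	TRUE
SIDT2-TAGLN	Y	N	N	Y	N		FALSE
SLC29A1-HSP90AB1	Y	Y	N	Y	N		FALSE
TRADD-B3GNT9	Y	Y	N	Y	N		FALSE
WRB-SH3BGR	Y	N	N	Y	N		FALSE
AZGP1-GJC3	Y	Y	N	Y	N		FALSE
BRCA1-VAT1	Y	N					FALSE
DTD2-HEATR5A	Y	Y	N	N	Y		FALSE
MBD1-CCDC11	Y	Y	N	Y	Y	Y	TRUE
RNF4-FAM193A	Y	Y	N	Y	N		FALSE
CTBS-GNG5	Y	N	N	Y	Y		FALSE
DHRS1-RABGGTA	N						FALSE
VAMP1-CD27-AS1	Y	N	N	N	N		FALSE
LMAN2-MXD3	Y	Y	N	Y	Y	Y	TRUE
POLA2-CDC42EP2	Y	Y	N	Y	N		FALSE
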