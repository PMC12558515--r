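# HLA class II hotspot cores of the Rh blood-group antigens, transcribed
# verbatim from the published hotspot-region table.
# antigen: RHD01 = the RhD normal-allele group (*RHD*01*, *RHD*01.01*,
#   *RHD*01W.2*, *RHD*01W.3*, which share identical hotspot lists);
#   RHD01W1 = *RHD*01W.1* (weak D type 1, p.Val270Gly); RHCE01 = *RHCE*01*.
# start: 1-based amino-acid start position of the 9-mer binding core.
# Known verbatim oddities preserved (no harmonization):
#   - RHD01 start 390 is "intracellular" in the DRB column but
#     "transmembrane" in the DQA-DQB column of the source table.
#   - RHD01W1 DQA-DQB rows 269/270 print the unsubstituted cores
#     (YVHSAVLAG/VHSAVLAGG) despite the Val270Gly substitution.
#   - RHCE01 DRB start 390 is "transmembrane" where the corresponding RhD
#     rows are intracellular; RHCE01 DQA-DQB 390 prints core LKIWKAPHE.
antigen	locus_group	start	core	region
RHD01	DRB	38	LEDQKGLVA	exofacial
RHD01	DRB	54	LTVMAAIGL	transmembrane
RHD01	DRB	98	LSQFPSGKV	exofacial
RHD01	DRB	125	ISVDAVLGK	transmembrane
RHD01	DRB	153	LRMVISNIF	transmembrane
RHD01	DRB	161	FNTDYHMNM	exofacial
RHD01	DRB	165	YHMNMMHIY	exofacial
RHD01	DRB	239	FNTYYAVAV	transmembrane
RHD01	DRB	250	VTAISGSSL	transmembrane
RHD01	DRB	269	YVHSAVLAG	transmembrane
RHD01	DRB	303	LISVGGAKY	transmembrane
RHD01	DRB	347	LVLDTVGAG	exofacial
RHD01	DRB	358	MIGFQVLLS	exofacial
RHD01	DRB	390	LKIWKAPHE	intracellular
RHD01	DRB	407	FWKFPHLAV	intracellular
RHD01	DQA-DQB	31	FTHYDASLE	transmembrane
RHD01	DQA-DQB	35	DASLEDQKG	exofacial
RHD01	DQA-DQB	45	VASYQVGQD	exofacial
RHD01	DQA-DQB	200	QTATIPSLS	transmembrane
RHD01	DQA-DQB	239	FNTYYAVAV	transmembrane
RHD01	DQA-DQB	253	ISGSSLAHP	transmembrane
RHD01	DQA-DQB	265	ISKTYVHSA	intracellular
RHD01	DQA-DQB	269	YVHSAVLAG	transmembrane
RHD01	DQA-DQB	270	VHSAVLAGG	transmembrane
RHD01	DQA-DQB	275	LAGGVAVGT	transmembrane
RHD01	DQA-DQB	358	MIGFQVLLS	exofacial
RHD01	DQA-DQB	390	LKIWKAPHE	transmembrane
RHD01	DQA-DQB	399	AKYFDDQVF	intracellular
RHD01	DPA-DPB	64	FLTSSFRRH	transmembrane
RHD01	DPA-DPB	69	FRRHSWSSV	transmembrane
RHD01	DPA-DPB	74	WSSVAFNLF	intracellular
RHD01	DPA-DPB	114	RLATMSALS	transmembrane
RHD01	DPA-DPB	156	VISNIFNTD	transmembrane
RHD01	DPA-DPB	264	KISKTYVHS	intracellular
RHD01	DPA-DPB	267	KTYVHSAVL	transmembrane
RHD01	DPA-DPB	269	YVHSAVLAG	transmembrane
RHD01	DPA-DPB	391	KIWKAPHEA	intracellular
RHD01	DPA-DPB	402	FDDQVFWKF	intracellular
RHD01	DPA-DPB	406	VFWKFPHLA	intracellular
RHD01	DPA-DPB	407	FWKFPHLAV	intracellular
RHD01W1	DRB	38	LEDQKGLVA	exofacial
RHD01W1	DRB	54	LTVMAAIGL	transmembrane
RHD01W1	DRB	98	LSQFPSGKV	exofacial
RHD01W1	DRB	125	ISVDAVLGK	transmembrane
RHD01W1	DRB	153	LRMVISNIF	transmembrane
RHD01W1	DRB	161	FNTDYHMNM	exofacial
RHD01W1	DRB	165	YHMNMMHIY	exofacial
RHD01W1	DRB	239	FNTYYAVAV	transmembrane
RHD01W1	DRB	250	VTAISGSSL	transmembrane
RHD01W1	DRB	269	YGHSAVLAG	transmembrane
RHD01W1	DRB	303	LISVGGAKY	transmembrane
RHD01W1	DRB	347	LVLDTVGAG	exofacial
RHD01W1	DRB	358	MIGFQVLLS	exofacial
RHD01W1	DRB	390	LKIWKAPHE	intracellular
RHD01W1	DRB	407	FWKFPHLAV	intracellular
RHD01W1	DQA-DQB	31	FTHYDASLE	transmembrane
RHD01W1	DQA-DQB	35	DASLEDQKG	exofacial
RHD01W1	DQA-DQB	45	VASYQVGQD	exofacial
RHD01W1	DQA-DQB	200	QTATIPSLS	transmembrane
RHD01W1	DQA-DQB	239	FNTYYAVAV	transmembrane
RHD01W1	DQA-DQB	253	ISGSSLAHP	transmembrane
RHD01W1	DQA-DQB	265	ISKTYVHSA	intracellular
RHD01W1	DQA-DQB	269	YVHSAVLAG	transmembrane
RHD01W1	DQA-DQB	270	VHSAVLAGG	transmembrane
RHD01W1	DQA-DQB	275	LAGGVAVGT	transmembrane
RHD01W1	DQA-DQB	358	MIGFQVLLS	exofacial
RHD01W1	DQA-DQB	390	LKIWKAPHE	transmembrane
RHD01W1	DQA-DQB	399	AKYFDDQVF	intracellular
RHD01W1	DPA-DPB	64	FLTSSFRRH	transmembrane
RHD01W1	DPA-DPB	69	FRRHSWSSV	transmembrane
RHD01W1	DPA-DPB	74	WSSVAFNLF	intracellular
RHD01W1	DPA-DPB	114	RLATMSALS	transmembrane
RHD01W1	DPA-DPB	156	VISNIFNTD	transmembrane
RHD01W1	DPA-DPB	391	KIWKAPHEA	intracellular
RHD01W1	DPA-DPB	402	FDDQVFWKF	intracellular
RHD01W1	DPA-DPB	406	VFWKFPHLA	intracellular
RHD01W1	DPA-DPB	407	FWKFPHLAV	intracellular
RHCE01	DRB	38	LEDQKGLVA	exofacial
RHCE01	DRB	54	LTVMAALGL	transmembrane
RHCE01	DRB	62	LGFLTSNFR	transmembrane
RHCE01	DRB	124	LISAGAVLG	transmembrane
RHCE01	DRB	130	VLGKVNLAQ	transmembrane
RHCE01	DRB	161	FNTDYHMNL	exofacial
RHCE01	DRB	165	YHMNLRHFY	exofacial
RHCE01	DRB	239	FNTYYALAV	transmembrane
RHCE01	DRB	250	VTAISGSSL	transmembrane
RHCE01	DRB	267	MTYVHSAVL	transmembrane
RHCE01	DRB	269	YVHSAVLAG	transmembrane
RHCE01	DRB	303	LISIGGAKC	transmembrane
RHCE01	DRB	358	MIGFQVLLS	exofacial
RHCE01	DRB	390	LKIWKAPHV	transmembrane
RHCE01	DRB	407	FWKFPHLAV	intracellular
RHCE01	DQA-DQB	31	FTHYDASLE	transmembrane
RHCE01	DQA-DQB	35	DASLEDQKG	exofacial
RHCE01	DQA-DQB	45	VASYQVGQD	exofacial
RHCE01	DQA-DQB	200	QRATIPSLS	transmembrane
RHCE01	DQA-DQB	239	FNTYYALAV	transmembrane
RHCE01	DQA-DQB	253	ISGSSLAHP	transmembrane
RHCE01	DQA-DQB	265	ISMTYVHSA	intracellular
RHCE01	DQA-DQB	269	YVHSAVLAG	transmembrane
RHCE01	DQA-DQB	270	VHSAVLAGG	transmembrane
RHCE01	DQA-DQB	275	LAGGVAVGT	transmembrane
RHCE01	DQA-DQB	358	MIGFQVLLS	exofacial
RHCE01	DQA-DQB	390	LKIWKAPHE	transmembrane
RHCE01	DQA-DQB	391	KIWKAPHVA	intracellular
RHCE01	DQA-DQB	398	VAKYFDDQV	intracellular
RHCE01	DQA-DQB	399	AKYFDDQVF	intracellular
RHCE01	DPA-DPB	64	FLTSSFRRH	transmembrane
RHCE01	DPA-DPB	69	FRRHSWSSV	transmembrane
RHCE01	DPA-DPB	74	WSSVAFNLF	intracellular
RHCE01	DPA-DPB	156	VISNIFNTD	transmembrane
RHCE01	DPA-DPB	160	IFNTDYHMN	exofacial
RHCE01	DPA-DPB	201	RATIPSLSA	transmembrane
RHCE01	DPA-DPB	263	RKISMTYVH	transmembrane
RHCE01	DPA-DPB	391	KIWKAPHVA	intracellular
RHCE01	DPA-DPB	402	FDDQVFWKF	intracellular
RHCE01	DPA-DPB	406	VFWKFPHLA	intracellular
RHCE01	DPA-DPB	407	FWKFPHLAV	intracellular
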