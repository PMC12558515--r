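# Per-allele HLA-DRB1 strong-binder (hotspot) start positions on the Rh
# antigens, transcribed verbatim from the published ethnicity-stratified
# hotspot table. RHD_normal = the *RHD*01.01*/*RHD*01W.2*/*RHD*01W.3*
# column; RHD01W1 = *RHD*01W.1*; RHCE01 = *RHCE*01*. Multiple hotspots per
# allele are semicolon-separated; an em-dash cell (no hotspot) is a blank
# field here. The source row for DRB1*04:08 lists start 390 with core
# YVHSAVLAG (a core that sits at 269 in every other row) for RHD_normal;
# preserved verbatim.
allele	antigen	starts	cores
DRB1*01:02	RHD_normal	250	VTAISGSSL
DRB1*01:02	RHD01W1	250	VTAISGSSL
DRB1*01:02	RHCE01	250	VTAISGSSL
DRB1*01:03	RHD_normal
DRB1*01:03	RHD01W1
DRB1*01:03	RHCE01	390	LKIWKAPHV
DRB1*03:01	RHD_normal	125	ISVDAVLGK
DRB1*03:01	RHD01W1	125	ISVDAVLGK
DRB1*03:01	RHCE01
DRB1*03:05	RHD_normal
DRB1*03:05	RHD01W1
DRB1*03:05	RHCE01	161	FNTDYHMNL
DRB1*03:06	RHD_normal	125	ISVDAVLGK
DRB1*03:06	RHD01W1	125	ISVDAVLGK
DRB1*03:06	RHCE01
DRB1*04:01	RHD_normal	269	YVHSAVLAG
DRB1*04:01	RHD01W1
DRB1*04:01	RHCE01	269	YVHSAVLAG
DRB1*04:02	RHD_normal	390	LKIWKAPHE
DRB1*04:02	RHD01W1	390	LKIWKAPHE
DRB1*04:02	RHCE01	130	VLGKVNLAQ
DRB1*04:07	RHD_normal	269	YVHSAVLAG
DRB1*04:07	RHD01W1	269	YGHSAVLAG
DRB1*04:07	RHCE01	269	YVHSAVLAG
DRB1*04:08	RHD_normal	390	YVHSAVLAG
DRB1*04:08	RHD01W1	269	YVHSAVLAG
DRB1*04:08	RHCE01	269	YVHSAVLAG
DRB1*04:14	RHD_normal	269	YVHSAVLAG
DRB1*04:14	RHD01W1
DRB1*04:14	RHCE01
DRB1*04:17	RHD_normal	269	YVHSAVLAG
DRB1*04:17	RHD01W1
DRB1*04:17	RHCE01
DRB1*04:18	RHD_normal	358	MIGFQVLLS
DRB1*04:18	RHD01W1	358	MIGFQVLLS
DRB1*04:18	RHCE01	358	MIGFQVLLS
DRB1*07:01	RHD_normal
DRB1*07:01	RHD01W1
DRB1*07:01	RHCE01	267	MTYVHSAVL
DRB1*07:03	RHD_normal
DRB1*07:03	RHD01W1
DRB1*07:03	RHCE01	267	MTYVHSAVL
DRB1*08:02	RHD_normal	269	YVHSAVLAG
DRB1*08:02	RHD01W1
DRB1*08:02	RHCE01
DRB1*08:09	RHD_normal	269	YVHSAVLAG
DRB1*08:09	RHD01W1
DRB1*08:09	RHCE01
DRB1*09:01	RHD_normal	269	YVHSAVLAG
DRB1*09:01	RHD01W1
DRB1*09:01	RHCE01
DRB1*10:01	RHD_normal	269	YVHSAVLAG
DRB1*10:01	RHD01W1
DRB1*10:01	RHCE01
DRB1*12:01	RHD_normal	303	LISVGGAKY
DRB1*12:01	RHD01W1	303	LISVGGAKY
DRB1*12:01	RHCE01
DRB1*12:02	RHD_normal	303	LISVGGAKY
DRB1*12:02	RHD01W1	303	LISVGGAKY
DRB1*12:02	RHCE01
DRB1*12:08	RHD_normal	303	LISVGGAKY
DRB1*12:08	RHD01W1	303	LISVGGAKY
DRB1*12:08	RHCE01
DRB1*13:02	RHD_normal
DRB1*13:02	RHD01W1
DRB1*13:02	RHCE01	165	YHMNLRHFY
DRB1*13:16	RHD_normal
DRB1*13:16	RHD01W1
DRB1*13:16	RHCE01	165	YHMNLRHFY
DRB1*13:31	RHD_normal
DRB1*13:31	RHD01W1
DRB1*13:31	RHCE01	165	YHMNLRHFY
DRB1*13:36	RHD_normal
DRB1*13:36	RHD01W1
DRB1*13:36	RHCE01	165	YHMNLRHFY
DRB1*15:01	RHD_normal	98	LSQFPSGKV
DRB1*15:01	RHD01W1	98	LSQFPSGKV
DRB1*15:01	RHCE01	390	LKIWKAPHV
DRB1*15:02	RHD_normal	98;239	LSQFPSGKV;FNTYYAVAV
DRB1*15:02	RHD01W1	98;239	LSQFPSGKV;FNTYYAVAV
DRB1*15:02	RHCE01	239;390	FNTYYALAV;LKIWKAPHV
DRB1*15:03	RHD_normal	98	LSQFPSGKV
DRB1*15:03	RHD01W1	98	LSQFPSGKV
DRB1*15:03	RHCE01	390	LKIWKAPHV
DRB1*15:04	RHD_normal	98;390	LSQFPSGKV;LKIWKAPHE
DRB1*15:04	RHD01W1	98;390	LSQFPSGKV;LKIWKAPHE
DRB1*15:04	RHCE01	390	LKIWKAPHV
DRB1*15:06	RHD_normal	98	LSQFPSGKV
DRB1*15:06	RHD01W1	98	LSQFPSGKV
DRB1*15:06	RHCE01	390	LKIWKAPHV
DRB1*15:07	RHD_normal	98	LSQFPSGKV
DRB1*15:07	RHD01W1	98	LSQFPSGKV
DRB1*15:07	RHCE01	390	LKIWKAPHV
DRB1*15:10	RHD_normal	98;390	LSQFPSGKV;LKIWKAPHE
DRB1*15:10	RHD01W1	98;390	LSQFPSGKV;LKIWKAPHE
DRB1*15:10	RHCE01	390	LKIWKAPHV
DRB1*15:11	RHD_normal	239	FNTYYAVAV
DRB1*15:11	RHD01W1	239	FNTYYAVAV
DRB1*15:11	RHCE01	390	LKIWKAPHV
DRB1*15:14	RHD_normal	98;239	LSQFPSGKV;FNTYYAVAV
DRB1*15:14	RHD01W1	98;239	LSQFPSGKV;FNTYYAVAV
DRB1*15:14	RHCE01	239;390	FNTYYALAV;LKIWKAPHV
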