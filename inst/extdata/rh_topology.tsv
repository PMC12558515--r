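# RECONSTRUCTED membrane-topology maps for the RhD and RhCE proteins
# (417 aa, 12 transmembrane segments, intracellular N- and C-termini).
# Coordinates are 1-based INCLUSIVE (not BED's 0-based half-open).
#
# The exofacial loops (32-53, 94-107, 158-167, 230-231, 282-290, 347-358)
# are taken from the published topology of the Rh proteins. The
# transmembrane/intracellular boundaries between them are NOT printed in
# that source: they were fitted once, by constraint satisfaction, so that
# the start-residue classification rule reproduces the published hotspot
# Region labels (see the package vignette). They are editable estimates,
# not measured boundaries.
#
# The RHCE01 map satisfies every published RhCE label. For RHD01 the
# published labels are internally contradictory at position 390
# (intracellular in the DRB column, transmembrane in the DQA-DQB column);
# this map follows the 2-of-3 column majority (intracellular from 390).
# The two maps therefore differ only at the TM12/C-terminus boundary.
antigen_id	start	end	label
RHD01	1	11	intracellular
RHD01	12	31	transmembrane
RHD01	32	53	exofacial
RHD01	54	72	transmembrane
RHD01	73	77	intracellular
RHD01	78	93	transmembrane
RHD01	94	107	exofacial
RHD01	108	130	transmembrane
RHD01	131	135	intracellular
RHD01	136	157	transmembrane
RHD01	158	167	exofacial
RHD01	168	185	transmembrane
RHD01	186	199	intracellular
RHD01	200	229	transmembrane
RHD01	230	231	exofacial
RHD01	232	263	transmembrane
RHD01	264	266	intracellular
RHD01	267	281	transmembrane
RHD01	282	290	exofacial
RHD01	291	313	transmembrane
RHD01	314	322	intracellular
RHD01	323	346	transmembrane
RHD01	347	358	exofacial
RHD01	359	389	transmembrane
RHD01	390	417	intracellular
RHCE01	1	11	intracellular
RHCE01	12	31	transmembrane
RHCE01	32	53	exofacial
RHCE01	54	72	transmembrane
RHCE01	73	77	intracellular
RHCE01	78	93	transmembrane
RHCE01	94	107	exofacial
RHCE01	108	130	transmembrane
RHCE01	131	135	intracellular
RHCE01	136	157	transmembrane
RHCE01	158	167	exofacial
RHCE01	168	185	transmembrane
RHCE01	186	199	intracellular
RHCE01	200	229	transmembrane
RHCE01	230	231	exofacial
RHCE01	232	263	transmembrane
RHCE01	264	266	intracellular
RHCE01	267	281	transmembrane
RHCE01	282	290	exofacial
RHCE01	291	313	transmembrane
RHCE01	314	322	intracellular
RHCE01	323	346	transmembrane
RHCE01	347	358	exofacial
RHCE01	359	390	transmembrane
RHCE01	391	417	intracellular
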