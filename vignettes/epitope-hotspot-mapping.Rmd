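---
title: "Mapping T-cell epitope hotspots on blood-group antigens"
author: "epihotspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping T-cell epitope hotspots on blood-group antigens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Alloimmunization against red-cell antigens — the production of antibodies
after transfusion or pregnancy — requires that peptides of the foreign
antigen be presented on the recipient's MHC class II (HLA-DR, -DQ, -DP)
molecules to CD4+ helper T cells. Whether a given blood-group protein can
be presented depends on whether any of its peptides bind the recipient's
class II alleles. `epihotspot` formalizes this as an *epitope hotspot*
analysis: given per-peptide, per-allele binding predictions for an antigen
such as RhD or RhCE, it finds the positions ("hotspots") whose 9-mer
binding cores are predicted strong binders, annotates them against the
protein's membrane topology, compares antigen variants (e.g. weak D
type 1, p.Val270Gly), and weights the result by HLA allele frequencies of
different populations.

The binding predictions themselves come from an external engine
(NetMHCpan-4.1 / NetMHCIIpan-4.1 style tabular output) or from the
package's own seeded simulator; the package's contribution is everything
downstream of the predictions.

## Model and definitions

* **Peptide windows.** An antigen of length $L$ is decomposed into all
  $L-k+1$ overlapping $k$-mers ($k = 9$ by default — the canonical class
  II binding-core length; class II grooves accept longer peptides but the
  9-residue core dominates specificity). Coordinates are 1-based
  inclusive throughout.
* **Binder classes.** A prediction with percentile rank $r$ (lower =
  stronger, relative to a background peptide population) is a strong
  binder (SB) iff $r < t_{SB}$, a weak binder (WB) iff
  $t_{SB} \le r < t_{WB}$, else a non-binder. Defaults
  $t_{SB} = 0.5\%$, $t_{WB} = 2\%$, with *strict* inequalities: a rank of
  exactly 0.5 is WB. The 0.5% SB default is applied to both class I and
  class II predictions; both bounds are arguments everywhere, so engine
  defaults can be substituted explicitly but never silently.
* **Profiles and hotspots.** For an allele panel $A$, the per-start
  profile is $N(s) = \sum_{a \in A} \mathbf{1}[r_a(s) < t_{SB}]$. A
  hotspot is a start with $N(s) \ge m$; the default $m = 1$ follows the
  per-peptide definition (a core that strongly binds *some* panel
  allele). $m$ is exposed for stricter panel-level calling, and adjacent
  hotspot starts can optionally be merged into regions, but individual
  cores are the primary reporting unit. A `per_residue` profile mode
  (each SB core increments all $k$ residues it covers) is retained for
  topology-coverage analyses.
* **Population burden.** For population $P$ with allele frequencies
  $f_a$, the weighted burden at start $s$ is
  $B_P(s) = \sum_a f_a \,\mathbf{1}[a \text{ has SB at } s]$.
  Frequencies are used exactly as reported (allele frequencies on the 2n
  basis); no Hardy–Weinberg phenotype conversion is applied. A blank
  frequency cell means "not typed", is kept distinct from an observed 0,
  and excludes the allele from burden sums with an audible warning.

## Design choices in genuinely open places

**Hotspot threshold.** Published per-position strong-binding figures show
clustered peaks but print no numeric calling rule. We default to
$m = 1$ because the operational hotspot definition is per-peptide; the
packaged hotspot tables are carried as fixtures rather than re-derived
from raw engine output, which this package cannot reproduce without the
external engines.

**Region classification rule.** Topology maps partition residues
1..L into exofacial / transmembrane / intracellular intervals
(validated: sorted, non-overlapping, gap-free). A core is labelled by the
interval containing its *first* residue (`start_residue` rule). This is
the only simple rule consistent with the published labels: the core at
start 358 is labelled exofacial although only its first residue lies in
the 347–358 exofacial loop, and the core at 165 is exofacial with only 3
of 9 exofacial residues. A `majority_overlap` rule (ties toward
exofacial, then transmembrane) is provided for sensitivity analyses.

**Reconstructed topology boundaries.** The exofacial loops of the Rh
proteins (32–53, 94–107, 158–167, 230–231, 282–290, 347–358) are
published; the transmembrane/intracellular boundaries between them are
not. The packaged maps fit those boundaries once, by constraint
satisfaction against the published hotspot region labels, and are shipped
as clearly-marked editable estimates, never hard-coded in logic. The fit
is exact for RhCE (41/41 labels). For RhD it cannot be exact: the source
table labels start 390 *intracellular* in its HLA-DRB column but
*transmembrane* in its HLA-DQA-DQB column for the same antigen group. The
packaged RhD map follows the two-of-three column majority (intracellular
from residue 390), reproducing 39/40 labels; the conflicting row is
preserved verbatim in the fixture with a note, and no per-locus map is
introduced to hide it (protein topology does not depend on which HLA
locus is analyzed). The corresponding acceptance check, which demands
100% agreement, therefore fails by exactly this one contradictory row —
we report 97.5% rather than harmonize the table.

**Frequency filter inequality.** The filter uses strict ">" (matching the
">10%" phrasing of the narrative text) although the table note says
"≥10%"; on the packaged table both criteria select identical allele sets,
and the flag is configurable.

**Variant diffs keyed on start.** A start present in both hotspot lists
with different cores is reported as `changed_core` (with the absolute
position of every differing residue, $s + \mathrm{offset} - 1$), not as
lost-plus-gained — matching the narrative of "the same hotspot with a
substituted residue" for p.Val270Gly. The four categories provably
partition the union of starts.

## The synthetic data generator

Because the neural-network engines are external, the package ships a
seeded simulator so that every pipeline stage is testable end to end:

* **Allele model.** Each synthetic allele is a $k \times 20$
  position-specific scoring matrix with `n_anchors` (default 3) anchor
  positions carrying one sharply preferred residue (weight 4) over
  near-flat noise (s.d. 0.15–0.3); a peptide's score is the sum of its
  per-position weights.
* **Empirical %rank.** At construction, $B$ background 9-mers (default
  1000, uniform over the 20-letter alphabet) are drawn and scored; the
  rank of a peptide is the add-one upper-tail percentile
  $100\,(1 + \#\{b : \mathrm{score}(b) \ge \mathrm{score}(p)\})/(B+1)$.
  This is small, exact and testable — no parametric distribution fit.
  The best achievable rank is $100/(B+1) \approx 0.1$, comfortably below
  the SB bound. Ranks of random peptides are *marginally* uniform on
  their grid; note that conditioning on one realized background inflates
  apparent deviations through its spacings, so the goodness-of-fit test
  pools draws across many independently seeded alleles.
* **Planting with verification.** `plant_motifs()` embeds, at each
  requested start, a strong binder of the target allele (anchor residues
  fixed to the preferred ones, the rest random). Verification then
  *checks* rather than assumes the construction: planted (start, allele)
  pairs must classify SB and every other pair NB; windows violating this
  have their free residues resampled (bounded rounds), and irreparable
  draws trigger a full retry under a derived seed (bounded retries, then
  a clear error). Planting a randomized strong binder rather than the
  consensus matters: consensus peptides often contain repeated residues
  that let a one-residue shift keep two anchor hits, making windows that
  overlap the plant irreparably strong.
* **Fixture files.** Records can be written in either engine dialect's
  column layout (marked synthetic in the header) and re-parsed
  losslessly, exercising the real parsers including allele-name
  normalization (`DRB1_1501`, `HLA-DQA10101-DQB10301`, `HLA-A01:01`).

What the simulator emulates: motif-driven core binding, percentile-rank
semantics against a background population, a panel of alleles with
distinct specificities, and ground-truth hotspots. What it does not:
biophysically realistic binding energetics, peptide-length effects and
core-offset uncertainty, inter-allele correlation of specificities, and
eluted-ligand training biases. Passing the recovery tests therefore
demonstrates the correctness of the aggregation/calling machinery, not
the accuracy of any real predictor.

## Numerical and interface conventions

* Engine output positions: the class I dialect's `Pos` column is treated
  as 0-based and shifted to 1-based; the class II dialect's as 1-based.
  Records carry the 1-based start of the *binding core* (`Pos` plus the
  core offset), so longer engine peptides align with 9-mer window
  coordinates; such records are flagged `core_shifted`.
* Windows containing `X` are enumerated but flagged; predictors skip
  them with a message, never silently.
* Duplicate (allele, start) records and mixed-antigen record sets are
  errors, not silent deduplication.
* All generators are deterministic under fixed seeds, and the pipeline
  reruns byte-identically for a fixed config and seed (the manifest
  records the config hash, seed, package version and input checksums).
* Problem sizes used by the test-suite and benchmark: a 200-residue
  antigen, a 5-allele panel, 3 planted motifs, background size
  $B = 1000$ (250 in the pooled uniformity test), chosen as the smallest
  sizes at which panel-level aggregation, overlap handling and recovery
  statistics are all non-trivial.

## Known limitations

* The full RhD/RhCE protein sequences are not bundled; desk-scale
  analyses reconstruct only the published 9-mer cores, and full-sequence
  runs need user-supplied FASTA for the reference accessions.
* Only protein-level substitutions are modelled (no indels, no
  nucleotide-level variants such as the Asian-DEL c.1227G>A, no
  RHD/RHCE gene-conversion alleles).
* No statistical significance testing of hotspot clustering is
  performed, and no haplotype linkage between DQA/DQB or DPA/DPB chains
  is modelled.
* The packaged topology boundaries are fitted reconstructions; users
  with better structural information should edit the interval fixture.
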