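Package: epihotspot
Title: T-Cell Epitope Hotspot Mapping for Blood-Group Antigens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps T-cell epitope hotspots on blood-group antigen proteins from
    peptide-MHC class II binding predictions. Reads antigen protein sequences,
    applies protein-level substitution variants (HGVS p. notation), enumerates
    9-mer binding cores, parses NetMHCpan-4.1/NetMHCIIpan-4.1 tabular output,
    classifies strong/weak binders by percentile rank, aggregates strong-binder
    counts across HLA allele panels into per-position profiles and hotspot
    calls, annotates hotspots against membrane-topology maps, compares antigen
    variants, and weights hotspot burden by population HLA allele frequencies.
    Includes a seeded position-specific scoring-matrix simulator that plants
    strong-binding motifs with known ground truth so the whole pipeline is
    testable without external prediction engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
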