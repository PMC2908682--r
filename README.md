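# mimdesign

Design and validation of artificial miRNA target mimics for plants.

Plant miRNAs direct RISC-mediated cleavage of near-perfectly complementary
mRNAs, cutting opposite mature-miRNA positions 10–11. Because most plant
miRNAs come in multigene families, whole-family loss of function is hard to
reach genetically. *Target mimicry* sidesteps this: a decoy transcript —
modelled on the *IPS1* non-coding RNA — carries a miRNA-complementary motif
with a three-nucleotide bulge opposite the cleavage position, so the loaded
RISC binds but cannot slice, and the miRNA is sequestered away from its real
targets.

`mimdesign` is for molecular biologists building such knockdown constructs.
Given mature miRNA sequences (miRBase-style FASTA) it:

* converts each miRNA (or subfamily consensus) into a non-cleavable decoy
  site: the reverse complement with the partner of position 11 replaced by a
  validated 3-nt bulge, so a 21-nt miRNA yields the classic 23-nt motif
  (length L − 1 + 3);
* scores miRNA:site duplexes under a positional penalty scheme (mismatch
  1.0, G:U wobble 0.5, bulge 1.0/nt, ×2 in the core region 2–13) and
  classifies each site `MIMIC_FUNCTIONAL` / `CLEAVABLE` / `INERT`;
* partitions families whose members diverge beyond wobble coverage into
  subfamilies, one mimic each (`MIM169defg`-style naming), via deterministic
  greedy set cover;
* predicts cross-family capture (which miRNAs a mimic cannot discriminate);
* splices the motif into a carrier backbone and designs overlap-extension
  mutagenesis primers (Wallace-rule Tm), with FASTA/GenBank/TSV outputs;
* ships a deterministic synthetic-catalogue generator, so the entire
  pipeline is testable with no downloads.

## Worked example

```r
library(mimdesign)

cat1 <- generate_mirna_set(fixture_spec(seed = 1, n_families = 2,
                                        members_per_family = 3))
cat1[, c("id", "sequence")]
#>            id              sequence
#> 1 xxx-miR101a AUGACAGGCCGGAAACCCCGA
#> 2 xxx-miR101b AUGACAGGCCGGAAACCCCGA
#> 3 xxx-miR101c AUGACAGGCCGGAAACCCCGA
#> 4 xxx-miR102a AACAACCCAUGGUGCCCCGUU
#> 5 xxx-miR102b AACAACCCAUGAUGCCCCGUU
#> 6 xxx-miR102c AACAACCCAUGAUGCCCCGUU

run <- run_design_pipeline(cat1)
run
#> <mim_design_run>
#>   miRNAs: 6 in 2 families -> 2 subgroups, 2 mimics
#>   off-target captures: 0; failed families: 0

run$mimics[["MIM101"]]
#> <mimic_site> MIM101: 23 nt, bulge AAA at [10,13), sources: xxx-miR101a, xxx-miR101b, xxx-miR101c

align_duplex(cat1[1, ], run$mimics[["MIM101"]]$site)
#> <duplex_alignment> (xxx-miR101a) 21-nt miRNA vs 23-nt site
#> 3' TACTGTCCGGAAA-CTTTGGGGCT 5'  site
#>    ||||||||||    ||||||||||
#> 5' AUGACAGGCC---GGAAACCCCGA 3'  miRNA
```

Each family collapses to one mimic here (family 102's single A/G difference
is absorbed by a G:U wobble in the consensus site). The diagram shows the
designed geometry: 10 Watson–Crick pairs, the 3-nt bulge (`AAA`) opposite
position 11 — which has no partner — and 10 more Watson–Crick pairs.
Classification of the three canonical central-site variants:

```r
m <- cat1[1, ]
validate_mimic(run$mimics[["MIM101"]]$site, m)$status       # "MIMIC_FUNCTIONAL"
validate_mimic(reverse_complement(m$sequence, "DNA"), m)$status  # "CLEAVABLE"
```

With a backbone (`generate_backbone()` or your own FASTA + motif TSV),
`run_design_pipeline(cat1, bb = bb, out_dir = "out")` also writes construct
GenBank files and a primer TSV. A thin command-line front end with the same
subcommands (`design`, `partition`, `validate`, `capture-matrix`,
`construct`, `primers`, `fixtures`) lives at `inst/scripts/mimdesign.R`.

See `vignettes/mimic-design.Rmd` for the duplex model, the
cleavability/capture predicates, and the reasoning behind every pinned
default.

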