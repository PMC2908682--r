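---
title: "Designing artificial miRNA target mimics: model and methods"
author: "mimdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing artificial miRNA target mimics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimdesign)
```

## The problem

Plant miRNAs guide ARGONAUTE-containing RISC complexes to slice mRNAs that
are near-perfectly complementary to the ~21-nt mature miRNA, cutting the
target opposite miRNA positions 10–11. Because plant miRNA families comprise
several genes producing identical or near-identical mature species, loss of
function for a whole family is hard to obtain by mutation. Target mimicry
offers a knockdown route: a decoy transcript carries a miRNA-complementary
motif that *binds* the loaded RISC but *cannot be sliced*, sequestering the
complex and de-repressing the genuine targets. The natural template is the
*IPS1* non-coding RNA, whose miR399-complementary motif carries a
three-nucleotide insertion opposite the cleavage position; the resulting
bulge in the miRNA/target duplex prevents endonucleolytic cleavage while
pairing elsewhere remains extensive.

`mimdesign` turns mature miRNA sequences into such decoy motifs, decides when
a family needs more than one mimic, predicts which other miRNAs a mimic will
inadvertently capture, and emits the final carrier construct plus
overlap-extension mutagenesis primers.

## The duplex model

A duplex pairs the miRNA (RNA, numbered 1..L from its 5' end) antiparallel
against a DNA site. Pair states are Watson–Crick (A:T, U:A, G:C, C:G), G:U
wobble (G:T, U:G with T standing in for U on the DNA site), or mismatch. The
alignment family searched by `align_duplex()` is global and end-to-end with:

* at most one contiguous internal loop in which `r` site bases and
  `m ∈ {0, 1}` miRNA bases are unpaired, with `r > m` (so the loop is always
  site-heavy — the mimic geometry is a site-side insertion, and miRNA-side
  bulges are out of the model);
* an optional unpaired run at the site 5' terminus, which faces the miRNA 3'
  end. This exists so a consensus site designed against the longest member
  of a family still aligns to 3'-shorter mature isoforms with the excess
  site bases dangling.

The designed geometry is the asymmetric 3×1 internal loop: the site partner
of miRNA position 11 is removed and a 3-mer inserted in its place, so a
21-nt miRNA yields a 23-nt motif (L − 1 + 3) and position 11 faces the bulge
with no partner. A strict "site-side-bases-only" bulge of width
`len(site) − len(miRNA)` cannot represent this (the net insertion is 2 nt
but the physical bulge is 3 nt), which is why the loop model carries the
extra looped-out miRNA base explicitly as a `mirna_loop` column.

### Scoring

Per column: Watson–Crick 0, wobble 0.5, mismatch 1.0, site-side unpaired
base 1.0 per nt; columns whose miRNA position (for bulges: nearest flanking
miRNA position) falls in the core region 2–13 are doubled. Looped-out miRNA
bases carry no extra charge — their cost is the widened site run they force.
These magnitudes follow the familiar plant target-prediction convention;
no single published formula is canonical, so they are pinned defaults,
configurable through `scoring_params()` and echoed into every JSON report.

Ties between minimum-score layouts are broken deterministically: fewest
mismatch columns first (this prefers the clean 3×1 loop over the
equal-scoring "2-nt bulge plus forced central mismatch" description of the
same duplex), then the smaller terminal dangle, then the smallest miRNA gap
index (leftmost bulge), then the smaller number of looped-out bases.

### Cleavability and capture

Two predicates classify a duplex, sharing the central window (miRNA
positions 9–12 by default):

* `is_cleavable()` — no site-side bulge intersects the central window, at
  most one non-Watson–Crick column sits at positions 9–11, and the total
  score is ≤ 4. This deliberately tolerates one central mismatch: a
  single-nucleotide mismatch at position 11 without a bulge does **not**
  abolish cleavage, so such sites classify as still cleavable.
* `is_capturing()` — a site-side bulge run of ≥ 3 nt lies inside the central
  window (both flanking paired miRNA positions within it), positions 2–9 are
  all paired Watson–Crick or wobble, and the score outside the bulge columns
  is ≤ 3.

Containment implies intersection, so the two predicates are structurally
mutually exclusive. Whether wobbles at positions 10–11 support cleavage in
vivo is not settled; the ≤ 1 non-WC rule is a pinned modelling decision.
`validate_mimic()` folds both into the trichotomy `MIMIC_FUNCTIONAL` /
`CLEAVABLE` / `INERT`.

```{r trichotomy}
m <- generate_mirna_set(fixture_spec(seed = 1, n_families = 1,
                                     members_per_family = 1))[1, ]
site <- design_mimic_site(m)
align_duplex(m, site$site)
validate_mimic(reverse_complement(m$sequence, "DNA"), m)$status  # "CLEAVABLE"
```

## Designing the site

`design_mimic_site()` builds the covering reverse complement (for a single
miRNA this is the exact complement; see below for subgroups), removes the
partner of position 11, and asks `choose_bulge_sequence()` for the 3-mer.
Candidates are scanned in fixed lexicographic order (A < C < G < T) and the
first one passing all clauses wins, making the design a pure function of the
input:

1. the minimum-score alignment of every source miRNA must place the 3-nt
   bulge at the intended interval with position 11 looped out — this rejects
   any candidate whose flanking bases re-pair with position 11 and thereby
   re-create a contiguous, potentially cleavable central duplex (the classic
   failure mode of keeping the original central sequence);
2. the site must not be cleavable and must capture every source;
3. the inserted 3-mer must not create a homopolymer run longer than 3 nt
   together with its flanks (runs not touching the bulge are the flanks' own
   business and are left alone).

Rejected candidates are logged with reasons in the design report. The bulge
sequences so chosen are deterministic but not necessarily the ones used
historically for any particular construct; the guarantee is the *constraint
set* (non-cleavable, capturing), not a unique sequence.

## Families, subfamilies, consensus coverage

`choose_site_base()` asks whether one DNA base can pair with every member
base observed at a position, exploiting wobble: {A, G} is covered by T and
{C, U} by G, whereas {A, C} is uncoverable. Candidates pairing more members
by Watson–Crick win; residual ties resolve T > G > C > A. With members
5'-anchored, a subgroup is *compatible* if every non-bulge position is
coverable and the resulting consensus mimic captures every member (shorter
members align with the excess site bases dangling at zero charge in the
capture score).

`partition_for_mimics()` grows a maximal compatible set from each member in
id order, then runs a greedy set cover (most uncovered members first, ties
to the smallest seed id), subtracting covered members so the output is a
partition. Greedy rather than exact cover keeps large families cheap; on
families of ≤ 6 members the test suite verifies the greedy size equals the
exhaustive-optimal partition size. `capture_matrix()` then aligns every
mimic against the whole catalogue; near-identical families show up as
off-target captures — the model's way of saying a mimic cannot discriminate
them.

Naming: one mimic for the whole family is `MIM<family>`; subfamily mimics
append the sorted variant letters (`MIM169defg`) or `.n` tokens
(`MIM161.1`).

## Constructs and primers

`assemble_construct()` splices the mimic site in place of the backbone's
motif interval (coordinates 0-based half-open internally, 1-based inclusive
in reports); flanks are untouched by construction and verified byte-exact in
tests. The 35S promoter/vector context is annotation only. Primer design
uses the Wallace rule Tm = 2(A+T) + 4(G+C) — closed-form and
dependency-free, so results are exactly reproducible; nearest-neighbour
models could be substituted but are deliberately not required. The mutagenic
primer carries the full mimic site with ≥ 20-nt backbone flanks, each flank
extended one base at a time until its own Tm reaches 55 °C; outer primers
anchor at the construct ends with Tm in [55, 63] °C. An in-silico
overlap-extension check — stitching the two implied PCR products by their
exact overlap — must reconstruct the construct byte-exactly.

## Synthetic fixtures

`generate_mirna_set()` emulates the family structure the design rules care
about: per family a uniform-random ancestor; optional subfamily blocks whose
ancestors differ by 5 *transversions* (A↔C, G↔U) placed outside the central
window; members differing from their block ancestor by ≤ 1 *transition*
(A↔G, C↔U). Transitions keep every block coverable by one wobble-exploiting
consensus site, and transversions guarantee no single base covers two
blocks, so planted partitions are exactly recoverable — besides mirroring
the transition bias of real sequence divergence. Block substitutions avoid
the central window so partition decisions are driven by non-central
pairing, like real subfamily divergence. The generator makes no attempt to
match miRBase composition biases, and passing tests on these catalogues
demonstrates the design logic, not performance on any particular genome;
real catalogues are user input and no miRBase release is pinned.
Everything is a pure function of the seed (`withr::with_seed`; backbones
use an offset stream so catalogue and backbone are independent).

## Numerical and edge-case choices

* Degenerate inputs: sites shorter than the miRNA are refused (miRNA-side
  bulges are out of the model); length differences beyond `max_site_bulge`
  (5 nt) are refused, and `capture_matrix()` marks such cells not-alignable.
* Mature lengths accepted: 18–26 nt (configurable in the parser).
* All randomness lives in the fixtures module; the design pipeline is
  seed-free, and repeated runs produce byte-identical output directories
  (no timestamps in any emitted file).
* Problem sizes exercised by the test suite, chosen to give property-style
  coverage at desk scale: 200 random miRNAs for the
  functional/cleavable/inert trichotomy, 1000 random short duplexes against
  an independent exhaustive-enumeration oracle, planted two-block families
  of 6 members (plus exhaustive partition search at 5 members), and 50
  random backbones for the overlap-extension round trip.

## Known limitations

* No thermodynamic (ΔG) hybridisation model and no secondary-structure
  folding of the decoy transcript; scoring is positional and additive.
* Capture is a binary, threshold-based prediction — no effect-size model for
  how strongly a mimic de-represses targets, and no kinetics of RISC
  sequestration.
* Primer design skips dimer/secondary-structure screening and restriction or
  recombination cloning simulation.
* The partition is provably minimal only at small family sizes; for larger
  families greedy cover is near-optimal but unverified.
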