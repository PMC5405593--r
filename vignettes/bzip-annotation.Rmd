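---
title: "Annotating bZIP domains: basic-hinge cores, leucine-zipper dimerization, and intron patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating bZIP domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bzipr)
```

## The model

Basic leucine zipper (bZIP) transcription factors carry a bipartite
domain: a DNA-binding *basic region* and *hinge*, followed by a
*leucine zipper* that mediates dimerization as a parallel coiled coil.
The basic-hinge core is remarkably regular across plants: an 18-residue
block with the invariant motif

```
N - X7 - R/K - X9
```

— an asparagine anchor, seven unconstrained residues, an arginine or
lysine, and a nine-residue hinge — with the first leucine of the zipper
starting immediately after the hinge. `bzipr` uses this motif itself as
the domain detector instead of a profile-HMM search: for a gene-family
survey the motif is the *definition* of the domain, every decision it
makes is auditable, and externally determined coordinates (e.g.
published HMM hits) can still be injected through a TSV and are then
checked rather than re-derived.

Positions are numbered in the field's convention: the first zipper
leucine is **+1**, the C-terminal hinge residue is **−1**, there is no
position 0, the anchor asparagine is **−18** and the basic R/K is
**−10**. The basic region is tracked up to **−26** where the protein
extends that far upstream, because that is the most upstream position
that participates in intron-pattern classification. Replacements at the
invariant sites −18 and −10 are flagged, not rejected: a hydrophobic
residue at −10 (seen in one strawberry clade-U protein) most likely
alters or abolishes DNA binding, and that is a finding worth reporting,
not an error.

```{r}
s <- paste0("MGG", "N", "TDEYRQW", "R", "AAKQSVKAE", "LEQKVHELE",
            "TRNAELQAE", "IAKLMKGQE")
dom <- find_bzip_domains(s, id = "demo")[[1]]
dom
check_invariants(dom)
```

## Heptad registration and dimerization

Coiled-coil heptads are labelled `g a b c d e f`. The first heptad (L0)
is anchored four residues *before* the first zipper leucine, so L0's
`g` sits at hinge position −4 and its `d` is the +1 leucine; all later
registers follow cyclically. Registration stops at the first of:

* a proline at or after +1 — a likely break in the α-helix
  (`helix_break`);
* a heptad whose `d` register holds none of L, I, V, M, F
  (`d_register_failure`) — that heptad is excluded, so the reported
  heptad count always equals the scanner's qualifying-heptad count;
* the end of the sequence (`sequence_end`), keeping a partial terminal
  heptad's occupied registers;
* nine complete heptads (`max_heptads`), the upper end of the two-to-
  nine heptad range observed in plant bZIP families.

A zipper needs at least two complete heptads to be accepted. The
`d`-register set `{L, I, V, M, F}` and the cap are arguments, not
constants.

Dimerization specificity is read from the charged residues flanking the
hydrophobic interface: the `g` position of one helix packs against the
`e` position of the partner (a *g↔e′* pair). Complete pairs — both
residues chargeable (R, K, E, D, and Q, which appears in the published
repulsive pair lists) — are classified by exact lookup against four
lists: attractive basic-acidic (R↔E, K↔E), attractive acidic-basic
(E↔R, E↔K, D↔K), repulsive basic (K↔K, R↔K, R↔Q, Q↔K, K↔Q) and
repulsive acidic (E↔E, E↔D, E↔Q, Q↔E). The lookup is *ordered*:
(R, E) is basic-acidic attractive while (E, R) is acidic-basic
attractive. Complete pairs outside all four lists (e.g. D↔R) are
reported as `complete_unlisted` rather than silently assimilated. Pairs
with exactly one chargeable residue are `incomplete_basic` or
`incomplete_acidic`; a lone glutamine counts on the acidic side, as the
amide of glutamate. These are design decisions of this package — the
published lists do not cover those cases — and both are trivial to
audit because every call is an exact lookup.

Two conventions exist for which `e` a `g` is paired with. In the
`gabcdef` register the `e` that *follows* a `g` lies within the same
heptad, which is the default here (`same_heptad`); the alternative
pairs `g` of heptad *k* with `e` of heptad *k+1* (`next_heptad`). The
source material for this analysis style does not state which it used,
so both are implemented and the choice is a single argument; it changes
pair attribution only, never register composition.

```{r}
z <- register_heptads(dom)
cat(format_zipper(z), sep = "\n")
ge_pairs(z)
```

Cohort statistics mirror the family-survey figures: pooled residue
frequencies at `a`, `d`, `e`, `g` (with charged fractions at `e`/`g`
over R, K, E, D only), the per-heptad fraction of asparagines at `a`
(Asn at `a` stabilizes a↔a′ contacts and favours homodimers), the
per-heptad frequency of each pair category, and a grouping of proteins
into dimerization *types* keyed on (heptad count, pair string). The
type grouping is a declared reconstruction — the published criteria
behind the 20 types reported for strawberry are not available — so the
number of types on real data is reported, not asserted.

## Intron patterns in the basic-hinge region

Splice phases are computed from CDS arithmetic in transcription order:
an intron's `cds_offset` is the number of coding bases 5′ of the
junction, and its phase is `cds_offset mod 3` (P0 between codons, P1
after the first base, P2 after the second). The GFF3 `phase` column is
deliberately ignored — it encodes the reading-frame offset of each CDS
segment, which is a different quantity that merely coincides with
splice phase in special cases. Stop codons included in the CDS by some
annotation dialects are trimmed when the CDS totals
`3 × protein length + 3`.

An intron "follows position *p*" when the junction falls directly after
the last base of *p*'s codon (phase 0) or inside the codon of the
residue after *p* (phases 1 and 2); the applied convention is recorded
per intron so an alternate reading can be audited. Introns mapped into
the −26…−1 window classify the gene into five patterns:

| pattern | evidence |
|---|---|
| a | one intron, P0, after hinge position −6 |
| b | one intron, P0, after −22 |
| c | one intron, P2, after −22 |
| d | two introns, both P0, after −26 and at hinge −5 |
| e | no intron in the region (intron-free genes are pattern e with an `intronless` flag) |

Evidence inside the window that matches none of a–d is classified
`unassigned`, never forced into the nearest class; real strawberry data
never needs that bucket, synthetic or novel data may.

## Protein descriptors

The descriptor set mirrors the standard ProtParam panel, with the
ProtParam conventions embedded as data so deviations from other tools
are explicable:

* **Molecular weight** — average isotopic residue masses plus one
  water.
* **Theoretical pI** — bisection root of the Henderson–Hasselbalch net
  charge over D, E, C, Y, H, K, R and both termini, with the
  Bjellqvist pK set including residue-specific N-terminal pKs;
  tolerance 0.005 pH for two-decimal reporting. Because the terminal
  pKs depend on the terminal residues, pI is invariant under
  permutations of the *interior* sequence only — the test suite asserts
  exactly that property.
* **Instability index** — `(10/L) · Σ` Guruprasad dipeptide weights;
  the only order-sensitive descriptor of the panel.
* **Aliphatic index** — `X(Ala) + 2.9·X(Val) + 3.9·(X(Ile)+X(Leu))` in
  mole percent.
* **GRAVY** — mean Kyte–Doolittle hydropathy.

Ambiguity codes (B, Z, X) are rejected rather than averaged; the
published strawberry proteins contain none. Reporting precision follows
the published table (MW 1 decimal, pI and the indices 2, GRAVY 3);
internal values keep full precision. A packaged copy of the published
50-protein descriptor table allows the summary statistics (mean length
402.54 aa, etc.) to be reproduced without any download.

## What the synthetic generator emulates — and what it does not

The generator is first-class, tested code, and its defaults are the
study conditions of the strawberry survey: 50 proteins; zippers of two
to nine heptads; 18% asparagine at the `a` register; Leu-dominated `d`
registers (the planted `d` distribution is restricted to the
hydrophobic set so the planted heptad count is the true zipper length);
half-charged `e` and `g` registers; and the intron-pattern mixture
a = 14, e = 14 (4 with decoy introns outside the region, 10 intron-free)
with the unpublished b/c/d remainder fixed once at 8/7/7. Unconstrained
positions are drawn from an alphabet that can seed neither a spurious
asparagine anchor nor an L/I/V/M/F `d` register, and every emitted
sequence is rejection-sampled (cap 1000, then an error rather than an
ambiguous fixture) until the scanner recovers exactly the planted core.
Gene models are built by back-translation with uniform synonymous
codons, GT…AG intron bodies of 60–500 bases, random flanking sequence,
and optional minus-strand emission with mirrored coordinates.

Passing round trips on this material establish that the coordinate
arithmetic, registration, classification and file I/O are mutually
consistent and strand-symmetric. They do **not** establish anything
about detection sensitivity on real proteomes: real sequences have
natural amino-acid background (spurious near-motifs), zippers
interrupted by imperfect heptads, and annotation noise that the
generator deliberately does not model. The two validation layers that
touch published numbers — the descriptor-table summary and the
descriptor recomputation from NCBI accessions — are therefore kept as
separate checks; the latter needs network access and reports itself as
unavailable without it.

## Numerical and validation choices

* Exported coordinates are 1-based inclusive, matching common
  annotation conventions; domain positions use the ± numbering with no
  zero.
* Overlapping candidate cores are resolved toward the candidate with
  more qualifying downstream heptads, ties to the leftmost — a
  deterministic rule that maximizes zipper evidence.
* Qualifying heptads are counted along the run of valid `d` registers,
  so a trailing heptad whose `d` exists but whose tail is truncated by
  the sequence end still counts for detection; acceptance of the
  *zipper* still requires two complete heptads.
* The scanner is verified against a brute-force window enumeration on
  1000 random short sequences; the pair classifier against an
  independent reimplementation on all 400 ordered residue pairs; intron
  patterns by 100 seeded round trips per pattern on both strands; and
  register/pair-category frequencies by exact recovery on a seeded
  50-protein cohort. These sizes are the package's validation
  conditions and are re-run by `scripts/acceptance.R`.
* `X` is accepted in input sequences but never satisfies a constrained
  motif position, and the descriptor functions reject it outright.

## Known limitations

* The motif scanner requires both anchors (N at −18, R/K at −10); it
  does not score degenerate cores. Published coordinate injection is
  the escape hatch for divergent family members.
* The zipper C-terminal boundary rule (proline break / `d` failure /
  nine-heptad cap) is a reconstruction of a convention the source
  literature delegates to earlier work; all terminations are logged
  with their reason so alternative rules can be compared.
* Dimerization typing is within-proteome string grouping; it does not
  enumerate heterodimer partners or compute coiled-coil energetics.
* Clade labels are accepted as input for cross-tabulation; no
  phylogeny is inferred.
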