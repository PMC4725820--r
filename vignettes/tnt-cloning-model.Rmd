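---
title: "The TNT cloning model: digestion, signatures, and assembly simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The TNT cloning model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tntsim)
```

This vignette explains what the simulator models, the assumptions it
makes, the geometric and numerical choices behind the implementation,
and what passing its tests does and does not say about real reactions.

## The system being modelled

TNT cloning joins DNA elements from one universal library (the entry
vector pSTART) into multi-gene constructs through repeated one-pot
digestion–ligation rounds, alternating between two destination-vector
families. The chemistry rests on three ideas:

1. **Two type IIS enzymes with nested sites.** EarI recognises
   `CTCTTC`, LguI recognises `GCTCTTC`; both cut downstream (one
   nucleotide on the top strand, four on the bottom), leaving 3-nt 5'
   overhangs. Because the EarI site is nested inside the LguI site, a
   vector region can be visible to both enzymes at once.
2. **Methylation splits the nested sites into two orthogonal ones.**
   When the composite context places a TCGA motif across the cleavage
   region (`...GCTCTT C G A...`), M.TaqI methylation of its adenines
   blocks cleavage by either enzyme. Alpha-family vectors carry their
   LguI release sites in this protected form: propagated in an
   M.TaqI-expressing host, they are inert during the EarI accept
   reaction and become cleavable again after a round of propagation in
   an ordinary strain. Omega-family vectors need no methylation at all:
   their EarI-only release sites (`ccCTCTTC`) are simply invisible to
   LguI.
3. **3-nt signatures direct the assembly.** Every overhang is one of a
   small set of 3-mers (signatures). Signatures 1 and 2 always flank a
   library insert; 3 and 4 join neighbouring inserts in binary (members
   1A+2) or ternary (1A+B+C) combinations. Because a junction is one
   codon, fused coding sequences stay in frame.

## Coordinates and cut geometry

All coordinates are 0-based, half-open, on the top strand; circular
positions are taken modulo length. For a top-strand recognition site of
length $m$ starting at $s$, the top nick sits at $s + m + 1$ and the
bottom nick three further; for a bottom-strand site the mirrored
formulae give $s - 4$ and $s - 1$. Every cut therefore exposes, as the
downstream fragment's 5' extension, the top-strand 3-mer at
`[cut, cut+3)` — the junction's signature. A fragment's reported size is
its cut-to-cut span, so sizes always partition the parent length
exactly; the single-stranded 3-nt tail is available separately as the
fragment footprint.

Blocking is evaluated per site from the molecule's mark set. A blocking
rule lists mark positions relative to the recognition site and an
efficiency in [0, 1]: M.TaqI 1.0 (near-complete inhibition), M.SacI
0.834 (partial), M.SssI 0.0 (none). Deterministic digestion treats a
site as blocked when a matching rule has efficiency at least 0.5;
stochastic (partial) digestion instead scales the per-site cut
probability by one minus the efficiency. A rule fires when **any** of
its marks is present, so hemimethylated duplexes remain protected. This
is a deliberate modelling choice: the ligation product of an accept
reaction is necessarily hemimethylated at the protected sites (the
incoming strand is unmethylated), and the platform demonstrably
accumulates those products, so hemimethylation must suffice to block.

## Signatures: reading conventions and the R members

Signatures are stored as read 5'→3' on the strand that carries them in
the primer/vector design: signature 1 on the top strand (`ACC`),
signature 2 on the bottom (`ATC`, junction top-strand `GAT`), exactly as
in the library primer templates. Signatures 3 and 4 are stored as their
top-strand junction 3-mers. Their concrete defaults (`AAT`, `ACT`) are
placeholders constrained by the grammar, not published values — the
system's behaviour is invariant to the concrete 3-mers given the
constraints, and a configuration can override them. Working out the
member geometry adds one constraint beyond pairwise distinctness and
non-complementarity: a signature that appears on both a left and a
right release flank of alpha members (3 and 4 both do) must start with
adenine **on both strands** — i.e. have the form `A·T` — because the
TCGA protection needs an adenine immediately after the spacer on
whichever strand carries the recognition site. `AGG`-style 3-mers
starting with A only on one strand cannot serve there.

The R (reversed) members store and release their insert in antisense
orientation. Capturing a standard s1/s2-flanked library insert
*backwards* forces the member's accept overhangs to be the reverse
complements of the standard accept junction duplexes; no independent
third 3-mer can do it. The package therefore derives the R accept
junctions as `revcomp(J2)`/`revcomp(J1)` and uses the configured
s1R/s2R values as the labels recorded on those junction features. The
observable contract is the published one: switching a member for its R
version flips the element's orientation and changes nothing else.

## The one-pot reaction and its fixpoint

`one_pot()` digests every pool molecule under the current methylation
state, builds the directed overhang-compatibility graph over fragment
ends (an edge where one fragment's bottom-strand overhang is the exact
Watson-Crick complement of another's top-strand extension), enumerates
every simple circular walk, and classifies the resulting circles. The
ligase model is perfect-fidelity: only exact 3-nt matches join, no
blunt ligation, no mismatches — the platform's published junction
accuracies are close enough to ideal that fidelity modelling is out of
scope. A product is *stable* when it retains no unblocked site of the
reaction enzyme; re-ligated inputs are by construction unstable and are
excluded. One digestion–ligation round already reaches the reaction's
fixpoint, because re-digesting any unstable product regenerates
fragments that are in the pool anyway.

One special case: a product assembled *into pSTART* keeps its
dual-enzyme flanking sites — that is the definition of a library entry
— so it can never be "stable". Products whose only open sites lie
inside the entry vector's annotated flank features are flagged
`entry_stable` and accepted when the destination is pSTART.

Diagnostics mirror what a bench user needs: overhangs offered by more
than one fragment end are reported as ambiguous junctions, and when no
productive product exists the unmatched junctions among the
*site-free* fragments (the only ones eligible for stable products) are
reported as dangling — omitting the middle element of a ternary set
names signatures 3 and 4.

## Member plasmid geometry

`make_member_plasmid()` synthesises each vector as a circular molecule:
release sites flanking the cloning region and accept sites inside the
stuffer pointing outward, so that accepting an insert excises the
stuffer together with both accept sites. Where a release junction
coincides with an accept junction (variant 1A left; variants 2 and C
right) the two cuts share one coordinate; elsewhere the release
junction abuts the accept junction directly, which is why a released
fragment carries at most one extra 3-mer per side and junction
bookkeeping stays in multiples of three. Backbones and the default
stuffer (a reporter placeholder standing in for white/blue screening)
are synthetic filler, deterministically generated per member and
scrubbed of every recognition and methyltransferase motif; resistance
markers are labels used in plan reporting only. Alpha members are
returned in their methylated ("propagated in the M.TaqI host") state.

## Planning and simulation

`plan_assembly()` chunks the element list left-to-right into groups of
three per level (a remainder of one is rebalanced to 2+2, so no
internal level carries a vacuous singleton transfer — the published
examples never exercise a mid-tree singleton, and the binary route is
always available), alternating families. The depth is
$1 + \lceil \log_3 n \rceil$ for $n \ge 2$, counting the level-1
library transfers as a cloning round, which reproduces the published
27-elements-in-4-rounds and 28-in-5 arithmetic. Orientation is consumed
at level 1: an antisense element simply goes to the R variant of its
assigned member.

`simulate_plan()` executes every step through `one_pot()` with the
destination family's accept enzyme, erases marks after each step
(propagation in an ordinary strain) and uses freshly methylated alpha
destinations. Every step must yield exactly one stable productive
product or the simulation aborts with that step's diagnostics. Element
order and orientation are read back from the final plasmid's
annotations, which is how the round-trip property (plan → simulate →
provenance equals the request) is tested. Because a level-1 transfer is
fully determined by its element and destination, batch simulations can
share a cache of transfer products, member plasmids and entry clones.

`insert_size()` predicts spans without sequences: a leaf's stored span
is the element length plus the two flanking junctions (6 nt); releasing
through a member adds 3 nt per side whose release junction differs from
the accept junction; joining $k$ inserts merges $k-1$ shared junctions.
The tests verify these predictions against the simulated sequences
base-for-base.

## Domestication and BlindSpot

`domesticate()` removes internal `CTCTTC`/`GAAGAG` sites from a CDS by
single synonymous codon edits. Candidate edits are ranked by the usage
rank of the *replacement* codon within its amino acid (an embedded
E. coli preference table), then by codon position; an edit must not
create a new site. This makes the output deterministic and biases it
toward well-used codons: `CTCTTC` (Leu-Phe) becomes `CTGTTC`, `GAAGAG`
(Glu-Glu) becomes `GAAGAA`.

`design_blindspot()` builds the 26-nt masking oligo: 11 nt upstream of
the 7-nt site window plus 8 nt downstream (covering the cleavage site),
on the strand reading `5'GCTCTTC3'` — if the sense strand reads
`GAAGAGC`, the antisense strand is used. For a plain `CTCTTC` site the
base immediately 5' of the motif completes the 7-nt window, so
11+7+8 = 26 always holds. Specificity is triaged by Hamming distance
between 26-nt windows, with a warning below 4 mismatches — the margin
at which the published discrimination data show masking collapsing to
~8% inhibition. The partial-digestion defaults are a per-site cut
probability of 0.625 (midpoint of the protocol's 60–65% digestion
progress) and inhibition 0.759 for a matched LguI oligo (0.499 for
EarI, a lower-confidence constant). No functional form links inhibition
to mismatch count — the data give two points — so inhibition is an
explicit parameter, and the modified-oligo chemistries are represented
only as parameter overrides. `simulate_blindspot()` reports both the
unconditional intended-product fraction and the fraction conditional on
all vector sites being cut, since both normalisations are natural and
they answer different questions.

## Primers, Tm, and polycistron arithmetic

Entry primers are the fixed library templates
(`ACATGCAGCTCTTCCACC`/`CGAGGAAGCTCTTCCATC` — LguI site, 1-nt spacer,
signature) plus an annealing region that starts at 20 nt and grows one
base at a time until the melting temperature reaches 50 °C. The Tm
model is a standard unified nearest-neighbour calculation at 50 mM
monovalent salt and 500 nM oligo, with the salt entering the entropy
term; any monotone model agreeing that an AT-only 20-mer melts below
50 °C would satisfy the design contract, and the parameters used are
logged with the output. The polycistronic arithmetic is the
independence model: $\text{eff}^{n-1}$ for $n$ genes sharing one mRNA
($0.997^9 \approx 97\%$), and $\text{flaw}^{\text{copies}}$ for tandem
self-splicing elements (20% → 4% with two copies).

## Synthetic data, problem sizes, and limitations

All test inputs are generated in code: band-geometry fixtures that
place EarI sites at prescribed cut coordinates (the 6,435-bp circular /
M.SacI and 1,055-bp linear / M.TaqI geometries, with filler scrubbed of
stray motifs), and random element libraries whose members are free of
internal sites even across the junction boundaries they will acquire
(CDS elements additionally stop-free and length 0 mod 3). The default
test problem sizes — 250–400 bp vector backbones, 60–240 bp elements,
up to 30 elements per plan, 10⁴ molecules per stochastic run — were
chosen so the full suite exercises every code path at interactive
speed; the geometry is length-invariant, so nothing about the model
changes at realistic plasmid sizes beyond runtime.

What the generator does **not** emulate bounds what green tests mean:
no ligation infidelity or blunt end-joining, no linear side-product
kinetics, no enzyme kinetics, star activity (the `aaCTCTTC` promiscuity
context is a warning diagnostic, optionally a configurable cut), no
transformation efficiency or colony statistics, and no triplex
thermodynamics behind the masking oligos. Passing tests show the
combinatorial, geometric and arithmetic layers of the platform are
implemented coherently — they are not evidence about wet-lab yields.
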