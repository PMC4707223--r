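---
title: "Coordination analysis of peptide variants: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordination analysis of peptide variants: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepcoord)
```

## The model

`pepcoord` treats a peptide tertiary structure as a labelled point set:
atoms with a chemical species (C/N/O/H), a residue index, and a
backbone/side-chain role.  All statistics derive from one object, the
histogram of interatomic distances, and three transformations of it:

1. the pair distribution function
   $g(r) = \frac{1}{2\pi N r^2 \rho_0}\sum_j\sum_{i>j}\delta(r - r_{ij})$,
2. the radial distribution function $R(r) = 4\pi r^2 \rho_0\, g(r)$,
3. the coordination number $n_{r_1 r_2} = \int_{r_1}^{r_2} R(r)\,dr$,
   with cumulative coordination $n(0, r)$ as the special case $r_1 = 0$.

The working hypothesis is that the *difference* of cumulative
coordination between a variant and the index peptide, averaged over the
5–7 Å window, correlates with immunological identity: positive
(over-coordinated) for agonist-like variants, negative
(under-coordinated) for antagonist-like ones, with magnitude ordering
functional strength.  Below ~5 Å, bond-length uniformity makes peptide
structures nearly indistinguishable ("coordination shell degeneracy");
beyond ~7 Å short-range order has faded.  The same analysis applied to a
7 Å environment shell or a whole pMHC–TCR complex dilutes the per-atom
signal — the metric is a peptide-scale observable, and the package
exposes the `peptide | shell | complex` scales explicitly so that this
negative control can be reproduced.

## Numerical conventions

**Binning.**  Bin $i$ covers the half-open interval
$[(i-1)\Delta r,\, i\Delta r)$ with $\Delta r = 0.1$ Å by default.  A
distance exactly on a boundary goes to the upper bin: the partition must
be exhaustive and deterministic, and boundary hits are measure-zero.
Bin-size robustness is tested: halving $\Delta r$ moves $n(0, 7\,Å)$ by
less than 1% on 9-mer structures.

**The $1/r^2$ prefactor** uses the bin centre $(i - \tfrac12)\Delta r$.
With that choice $R\cdot\Delta r = 2\,\mathrm{counts}/N$ holds *exactly*,
so every coordination integral — the quantity the classification rests
on — is independent of the centre convention.  This identity is also the
package's main internal oracle: cumulative coordination must equal
$2\times$ (pairs closer than the bin edge) $/N$ to $10^{-9}$, and the
full-range total must equal $N-1$ exactly.

**Box volume.**  $V$ is the axis-aligned bounding box of the selected
atoms with zero margin (a `box_margin` option exists, and generators
with a known box pass `volume` explicitly).  Published absolute
densities for the study peptides imply a larger box than a zero-margin
bound, so absolute $\rho_0$ values are convention-dependent and only the
ratio mass density / number density — which cancels $V$ and equals the
mean atomic mass times 1.66054 — is asserted numerically.

**Partial normalisation.**  Partials (C-C, C-N, …) are normalised with
the *total* structure's $N$ and $\rho_0$.  The alternative (per-species
pair counts) destroys additivity; with the shared convention the partial
curves sum bin-by-bin to the total, which is enforced to $10^{-9}$.

**Peak reporting.**  First-shell peak positions are reported as the
lower edge of the argmax bin below 2 Å (distances quoted to one decimal
at the default bin), matching how bonded C-C (1.5 Å) and C-N (1.3 Å)
spacings are conventionally quoted.

**Degenerate inputs.**  Duplicate atoms (zero-distance pairs) are an
error naming the offending structure, not a bin-0 count.  Structures
with coplanar atoms have no bounding-box volume; bulk properties error
rather than report infinities.  Histograms need at least two selected
atoms.  Coordination deltas require identical grids (bin size and
range); the pipeline enforces a common `r_max` across structures.

## Protonation as a geometric stand-in

Crystal structures resolved by X-ray diffraction carry no hydrogens.
The reference treatment relaxes added H atoms quantum-chemically with
heavy atoms frozen; `pepcoord` instead places hydrogens at ideal
sp²/sp³ geometry with fixed bond lengths (C-H 1.09, N-H 1.01, O-H 0.96,
S-H 1.34 Å), rotatable hydrogens staggered/trans relative to the
heavy-atom frame, fully deterministic.  Consequences, stated once and
relied on throughout:

- heavy-atom statistics (total and C/N/O partials) are *identical* to
  the unprotonated analysis plus a change of $N$ and $\rho_0$;
- H-partial results (C-H, H-H) are qualitative — dominant-group
  identification in the decomposition is meaningful, printed percentage
  values that depend on relaxed H positions are not reproduced;
- termini are zwitterionic by default (NH₃⁺ / COO⁻), tyrosine phenols
  can be deprotonated (the "u" variants), Asp/Glu are deprotonated and
  Lys/Arg protonated as at neutral pH, His uses the neutral Nε2-H
  tautomer (a generality decision; the study peptides contain no His,
  Asp, Glu or Lys);
- formal charge and spin state are electronic-structure metadata with no
  geometric effect here, so they are not modelled.

## Short-range-order cluster statistics

For clusters centred on a species (C, N or O), neighbours of any species
within the 4 Å cutoff are counted (total CN).  The cluster volume
convention — a sphere of radius equal to the cutoff, central atom
included in the counts — is the simplest literal reading of "clusters
centred on a species"; published per-cluster density bars use an
unstated convention, so comparisons there are qualitative.  The
histogram-weighted mean neighbour distance is
$\sum x_i N_i / \sum N_i$ with $x_i$ the bin centres.

## Decomposition and classification

Every selected pair with distance in the window (default 5–7 Å)
contributes its $2/N$ coordination share to exactly one group keyed by
the unordered pair of (residue, role), e.g. `2B6S`.  Group sums
partition the windowed coordination exactly.  Variant and index tables
are matched by residue index and role with missing groups as zero, and
compared without per-atom renormalisation: the sums are already
per-structure-atom quantities, and the substituted residue's side chain
legitimately differs in atom count.  The focus percentage is the signed
ratio of the focus-group deviation to the total deviation; because
groups can partially cancel, the magnitude may exceed 100% (flagged),
and the share of absolute deviations is emitted alongside.

Classification averages the delta over the window rather than taking
the point value at 7 Å — robust to single-bin noise, and centred where
the signal is localised.  The dead band separating noise from signal
defaults to 0.05 coordination units; no threshold is inherited from the
reference analysis, this one separates float noise from planted signals
on the study-scale structures.  Only sign + magnitude ordering is
claimed; no quantitative mapping from magnitude to functional avidity
classes is attempted.

## The synthetic world

The generator emulates exactly what the statistics can sense:

- 9-residue chains, idealized backbone bond lengths (N-CA 1.46,
  CA-C 1.52, C-N 1.33, C-O 1.23 Å) so the first-shell C-C/C-N peaks land
  on 1.5/1.3 Å as in any real peptide;
- side-chain sizes defaulting to the 9-mer epitope profile
  (4,4,7,0,8,3,3,8,3 heavy atoms), or idealized standard residues
  (templates for A, R, F, G, L, P, V, Y) when a sequence is given —
  enough to build labelled stand-ins for LLFGYPVYV and its variants;
- torsions sampled from extended-region distributions with a 2.4 Å
  clash floor and bounded retries (mirror puckers for proline rings);
  chain-level restarts keep generation deterministic under the seed;
- planted truths: uniform dilation by $f$ lengthens every pair distance,
  so $f > 1$ *must* read under-coordinated and $f < 1$ over-coordinated;
  compacting one residue's side chain *must* put 100% of the deviation
  in that residue's S-groups; i.i.d. uniform clouds *must* have
  $g \approx 1$.

What a green test does establish: the estimators, conventions and the
classification logic are correct on structures whose ground truth is
known by construction.  What it does not establish: that crystal
conformations of the study peptides reproduce the published deviation
percentages and sign patterns — those depend on real coordinates that
cannot be bundled, and the corresponding acceptance check stays red
until the four PDB entries are supplied under `inst/extdata/real/`.

## Known limitations

- No periodic boundary conditions and no finite-size edge correction to
  $g(r)$; peaks are compared by position, not height.
- Bounding-box volume is a convention; absolute densities are not
  comparable across box conventions.
- Geometric protonation yields qualitative H-partials only.
- Synthetic chains are not Ramachandran-faithful and carry no rotamer
  library or force field; they are statistical stand-ins, not
  conformational predictions.
- Peptide chains are selected by user-supplied chain ID; no automatic
  antigen detection across PDB dialects.
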