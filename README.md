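# pepcoord

Short-range atomic order as a structural readout of peptide immunological
identity.

T-cell responses to a peptide presented by an MHC molecule can flip from
agonism to antagonism on a single residue substitution, while binding
energetics stay nearly degenerate.  `pepcoord` implements a
coordination-based alternative: compare the *cumulative atomic
coordination* of each variant peptide's tertiary structure against the
native (index) peptide over the 5–7 Å short-range-order window.
Over-coordinated variants lean agonist-like, under-coordinated variants
antagonist-like, and the magnitude of the difference orders functional
strength.  The package targets structural bioinformaticians working with
pMHC–TCR crystal structures (e.g. the HTLV-1 Tax 9-mer LLFGYPVYV and its
single-substitution variants) and anyone who needs pair-correlation
statistics on small molecular structures.

## The statistics at the core

From the interatomic distance histogram of a structure with `N` atoms in
a box of volume `V` (number density `ρ₀ = N/V`), binned at `Δr = 0.1 Å`:

- **Pair distribution function**
  `g(r) = 1 / (2π N r² ρ₀) · Σᵢ Σⱼ>ᵢ δ(r − rᵢⱼ)` — peaks mark preferred
  interatomic spacings (1.5 Å C–C and 1.3 Å C–N bonds dominate the first
  coordination shell of any peptide).
- **Radial distribution function** `R(r) = 4π r² ρ₀ g(r)` — the `r²`
  weight shifts emphasis onto the 5–7 Å range where the discriminating
  signal lives.
- **Coordination number** `n(r₁, r₂) = ∫ R(r) dr` — with `r₁ = 0`, the
  cumulative coordination `n(0, r)`.  Per bin, `R·Δr = 2·counts/N`
  exactly, so every coordination integral is independent of the bin-centre
  convention.
- **Coordination delta** `Δn(r) = n_variant(0, r) − n_index(0, r)` — the
  discriminating metric; its 5–7 Å mean drives the identity call.
- **Decomposition**: the windowed coordination is partitioned exactly onto
  backbone/side-chain residue-interaction groups (`"2B6S"` = backbone of
  residue 2 against side chain of residue 6), quantifying how much of a
  variant's deviation is carried by the substituted residue's side chain.

Species-pair partials (C-C, C-N, …) share the total structure's `N` and
`ρ₀`, so partial curves sum bin-by-bin to the total.  A deterministic
geometric protonation (ideal sp²/sp³ hydrogen placement, heavy atoms
immobile, zwitterionic termini) stands in for quantum-chemical H
relaxation, so H-partial results are qualitative.

## Worked example

Everything below is computable offline: synthetic stand-ins built from
the real sequences (idealized geometry, seeded torsions — labelled
`*_synthetic` because they are not crystal conformations).

```r
library(pepcoord)

tax <- synthetic_peptide("LLFGYPVYV", seed = 1, label = "Tax_synthetic")
p6a <- synthetic_peptide("LLFGYAVYV", seed = 1, label = "P6A_synthetic")

bulk_properties(tax)
#> N = 77, V = 5607.9 A^3, rho0 = 0.013731 atoms/A^3, density = 0.293341 g/cm^3

first_shell_peak(pdf_from_histogram(build_histogram(tax, "C-C")))
#> [1] 1.5    # A: the bonded C-C spacing

rep <- run_pipeline(run_config(index = tax, variants = list(P6A = p6a)))
rep$scales$peptide$calls$P6A
#> <identity_call> P6A vs Tax_synthetic [total]: under_coordinated
#>   (antagonist-like), mean delta 5.0-7.0 A = -1.585
rep$contributions[["P6A C-C"]]
#> <contribution_report> P6A vs Tax_synthetic [C-C] 5-7 A: residue 6 side
#>   chain carries 67.9% of the deviation (abs share 42.9%)
```

Reading the output: 77 heavy atoms (56 C, 9 N, 12 O — the LLFGYPVYV
composition), a mass/number-density ratio of 21.36 Da (= the mean
heavy-atom mass × 1.66054), the first-shell C-C peak on the 1.5 Å bin,
and a variant that is under-coordinated relative to the index by ~1.6
atoms per atom on average across 5–7 Å, with about two thirds of the
(signed) deviation carried by the substituted residue-6 side chain.  On
real crystal structures the same pipeline is run via `read_pdb(path,
chain = "C")` for each entry, or from the command line:

```sh
Rscript inst/cli/pepcoord.R analyze --config run.yaml
Rscript inst/cli/pepcoord.R simulate --sequence LLFGYPVYV --seed 1 --out tax.pdb
Rscript inst/cli/pepcoord.R classify --index tax.pdb --variant v1.pdb --variant v2.pdb
```

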