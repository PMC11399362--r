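---
title: "Designing host-excluded circular probes for RCA assays"
author: "circProbe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing host-excluded circular probes for RCA assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circProbe)
```

## The design problem

Rolling circle amplification (RCA) detects a short nucleic-acid target by
hybridising it to a single-stranded circular DNA probe and letting a
strand-displacing polymerase copy the circle into a long concatemer. The
probe used here is assembled from **four 20-nt arms**, each complementary to
a distinct site on the target mRNA, concatenated into an 80-nt linear oligo
and enzymatically circularised (single-stranded ligases accept substrates of
roughly 80–100 nt, which the 4 × 20 design meets at the lower bound).

Specificity is the central constraint: if any stretch of the probe also
hybridises host (background) RNA, the assay amplifies the wrong template.
The design rule adopted here is *exact host exclusion at the 16-mer level*:
no 16-mer of the probe's target-facing sequence — whether inside an arm or
spanning the boundary where two arms are joined — may occur anywhere in the
host transcriptome.

## The host 16-mer index

Every 16-mer of every host sequence (windows sliding by 1, i.e. adjacent
16-mers overlap by 15 bases) is packed into a 32-bit integer with 2 bits per
base (A=00, C=01, G=10, T=11, first base most significant). The code space
is exactly $4^{16} = 2^{32}$, so presence can be stored as one bit per
possible code: a bitmap of $2^{32}$ bits = 536,870,912 bytes = **512 MB**,
a size that is constant no matter how many sequences are indexed. Lookups
are a single bit test; the index can be saved and reloaded bit-exactly.

Numerical choices worth stating:

* **Encoding order.** Any fixed bijection works; this one makes numeric
  order of codes coincide with lexicographic order of 16-mers, which is
  convenient for debugging and for the sorted set backend.
* **On-disk bit order.** Code $c$ lives at bit $c \bmod 8$ of byte
  $\lfloor c/8 \rfloor$ (little-endian within the byte). The layout is part
  of the file format (magic `ROAIDX`, a version byte, fixed-width counts,
  then the raw bitmap) so files are portable across machines.
* **Alphabet.** Input is normalised to upper-case DNA with U mapped to T,
  so one index serves RNA and DNA inputs. Windows containing any other
  letter (N and the IUPAC ambiguity codes) are *skipped*, not errors —
  real transcriptome FASTA files contain them.
* **Strand.** Only the given (sense) strand is indexed and screened,
  matching an RNA-target-versus-host-RNA workflow.
* **Set backend.** `buildHostIndex(..., backend = "set")` stores the sorted
  distinct codes instead of the bitmap. It answers every query identically
  (this equivalence is asserted in the test suite) and is what the small
  examples below use; the bitmap remains the default, and the 512 MB size
  claim applies to it.

```{r index}
fx <- generateFixturePair(hostLength = 2000, targetLength = 400, seed = 7)
idx <- buildHostIndex(fx$host, backend = "set")
idx
```

## Candidate screening

The target mRNA is cut into 20-mers with an overlap of 19 bases (one
candidate per start position). Each 20-mer contains exactly five 16-mers
(starts 0–4); a candidate is **host-clean** only if none of the five occurs
in the index. A consequence used throughout the tests: a 16-mer shared with
the host at target position $p$ invalidates exactly the candidate starts in
$[p-4,\,p]$.

Host-clean candidates then pass composition filters. The thresholds are
deliberate design choices (standard oligo-design practice; none is a claim
about the assay chemistry) and all are configurable via `filterConfig()` or
a flat YAML file:

| check | default | rationale |
|---|---|---|
| GC fraction | 0.40–0.60 | balanced duplex stability |
| $T_m$ method | `gc_adjusted`: $64.9 + 41\,(n_{GC} - 16.4)/N$ °C | standard short-oligo estimate; Wallace rule $2(n_A+n_T)+4(n_G+n_C)$ available |
| $T_m$ range | 50–65 °C | brackets the 57–60 °C working temperature of the isothermal reaction |
| homopolymer run | ≤ 4 | synthesis/hybridisation artifacts |
| 3′ end | G or C required | "3′-end specific base" read as a GC clamp, the common interpretation; can be disabled |

```{r screen}
scr <- screenCandidates(idx, fx$target)
table(host_clean = scr$host_clean, composition_pass = scr$composition_pass)
```

## Junctions and site selection

Joining two 20-mers head-to-tail creates a 40-nt sequence whose
boundary-spanning 16-mers exist in neither site alone; they too must be
absent from the host. Because "the 16-mer at the junction" is ambiguous,
two modes are offered: `"center"` checks only the 16-mer centred 8+8 on the
boundary; the default `"all"` checks all 15 spanning 16-mers
(concatenation starts 5–19), a strict superset and therefore the
conservative choice. The probe is circular after ligation, so the
wrap-around junction from the fourth arm back to the first is checked
exactly like the three internal ones.

"Evenly distributed" sites are made precise as follows: ideal anchors sit
at the quartile centres $(i + 0.5)/4 \cdot L$ of the target
($i = 0\ldots3$); for each anchor the valid sites are ranked by
$|\text{site centre} - \text{anchor}|$ with leftmost start breaking ties; a
deterministic depth-first search over these rankings — enforcing ascending
starts, a start gap of at least 20 nt (non-overlap; no larger minimum gap
is imposed), and clean junctions including the wrap-around — returns the
first complete assignment. That is the lexicographically best feasible
per-anchor distance vector, reproducible and testable against an
exhaustive 4-subset search (which the acceptance tests perform at up to
12 sites).

Arms are concatenated with no spacer bases, in genomic order; the sentence
defining the joining order of the original protocol is ambiguous, and
genomic-order concatenation is the one reading consistent with the ordered
junction validation, so it is enforced rather than guessed around. The
80-nt probe is reported with its reverse complement — the strand one
actually synthesises and ligates, since it is the strand complementary to
the target — plus the four per-arm reverse complements.

```{r design}
pd <- designProbe(idx, fx$target)
pd
```

## Quantity conversion

`molesPerMicroliter()` converts a measured mass concentration to molarity
using the average nucleotide molecular weight of 330 pg/pmol:
$$\frac{\mu g}{mL} \times \frac{mL}{1000\,\mu L} \times \frac{pmol}{330\,pg}
  \times \frac{10^6\,pg}{\mu g} \times \frac{1}{N}
  = \frac{pmol}{\mu L},$$
where $N$ is the number of nucleotides. The conversion is exactly
invertible, which the tests verify to $10^{-12}$ relative tolerance.

```{r quant}
molesPerMicroliter(3.3, 100)
```

## What the synthetic fixtures do and do not show

`generateFixturePair()` produces a host and a target of i.i.d. random bases
at a chosen GC bias (default 0.5), with `nPlanted` 16-mers copied verbatim
from random host positions into the target at recorded positions. Plants
are spaced at least 36 nt apart so each one's rejection window $[p-4, p]$
is disjoint from the others and no single 20-mer overlaps two plants —
ground truth is then exactly enumerable, and `truthEval()` scores the
screening stage against it (by soundness of an exact index,
`falsely_retained` must always be 0).

The default scale is a 10 kb host and a 1 kb target. For i.i.d. sequence
the chance that a random target 16-mer collides with a 10 kb host is about
$10^4/2^{32} \approx 2\times10^{-6}$ per window, so unplanted rejections
are rare and every one is cross-checked against a literal substring search.
These fixtures emulate the *combinatorics* of host exclusion, not real
transcriptomes: no splicing, no repeat families, no expression weighting,
no shared evolutionary ancestry between host and target. Passing tests
therefore demonstrate algorithmic correctness (agreement with brute-force
string oracles, exact rejection windows, deterministic selection), not
that four clean arms exist for any particular real virus/host pair — on
real data the candidate pool can be far sparser, and the design step
reports failure (exit code 3 from the CLI) when fewer than four compatible
sites exist.

Problem sizes used by the automated checks — chosen so every brute-force
oracle (string sets, exhaustive 4-subset search) stays exact and fast:
hosts of 1–10 kb, targets of 0.4–1 kb, up to 12 sites for the selection
oracle, 1,000 random membership probes, 10,000 random 16-mers for the
encoding bijection property.

## Degenerate inputs and edge behaviour

* Sequences shorter than the window yield empty enumerations; a target
  shorter than 20 nt is an input error.
* Windows with non-ACGT letters are skipped everywhere (indexing and
  screening), so an N never silently matches anything.
* Zero surviving candidates is not an error at the screening stage; the
  assembly stage raises a design failure naming the limiting constraint.
* `addSequences()` never clears a bit (monotone growth) and returns a new
  index; the original handle is unchanged.
* Ties in site selection are broken by leftmost start, making the whole
  pipeline deterministic: identical inputs give byte-identical outputs.

## Known limitations

* Exact 16-mer exclusion is the only off-target criterion: no
  thermodynamic nearest-neighbour $\Delta G$, no hairpin/dimer screening,
  no alignment-based search for near-matches (a host site with 15 of 16
  matching bases passes).
* k is fixed at 16; the bitmap trick relies on $4^k$ fitting an
  addressable bit space.
* Only the sense strand is considered on both sides.
* The four arms are constrained to non-overlap (gap ≥ 20 nt) but no larger
  minimum separation is imposed.
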