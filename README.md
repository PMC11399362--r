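# circProbe

Host-exclusion design of circular (padlock-style) DNA probes for rolling
circle amplification (RCA) detection assays.

## The problem

RCA-based assays detect a nucleic-acid target by hybridising it to a
single-stranded circular probe and amplifying the circle into a long
concatemer. The probe here is built from **four 20-nt arms**, each
complementary to a distinct site on the target mRNA, concatenated into an
80-nt oligo (within the 80–100 nt substrate window of single-stranded
circularisation ligases) and ligated into a circle. The probe must not
cross-hybridise the host (background) transcriptome, or the assay amplifies
the wrong template. `circProbe` is for anyone designing such probes — e.g.
a viral mRNA target against a bacterial host background.

## The method

1. **Host 16-mer index.** Every 16-mer of the host (windows sliding by 1)
   is packed into a 32-bit code with 2 bits per base (A=00, C=01, G=10,
   T=11). Presence is one bit per possible code: a bitmap of 2^32 bits =
   **512 MB**, constant regardless of how many sequences are indexed, with
   O(1) lookups and bit-exact save/load. A sorted-set backend answers
   identically for small hosts.
2. **Candidate screening.** The target is cut into 20-mers (overlap 19).
   Each 20-mer contains five 16-mers (starts 0–4); the candidate survives
   only if *none* of the five occurs in the host
   ("host-clean"). Survivors then pass composition filters: GC in
   [0.40, 0.60], T_m = 64.9 + 41 (n_GC − 16.4)/N in [50, 65] °C (Wallace
   rule available), homopolymer runs ≤ 4, and a 3′ G/C clamp — all
   configurable.
3. **Junctions and selection.** Joining arms head-to-tail creates new
   boundary-spanning 16-mers; these must also be absent from the host
   (default: all 15 spanning 16-mers; optionally just the centred one).
   Four sites are chosen nearest to the quartile anchors
   (i + 0.5)/4 · L by a deterministic backtracking search requiring
   non-overlap and clean junctions, including the wrap-around that closes
   the circle.
4. **Outputs.** The 80-nt probe, its reverse complement (the strand to
   synthesise and ligate), the four per-arm reverse complements, and TSV
   reports of every screening decision.

It also ships a seeded synthetic fixture generator with planted shared
16-mers (`generateFixturePair()`/`truthEval()`) and the mass-to-moles
conversion `molesPerMicroliter()` (µg/mL → pmol/µL at 330 pg/pmol per
nucleotide).

## Worked example

```r
library(circProbe)

# a synthetic host transcriptome (2 kb) and target mRNA (400 nt)
fx <- generateFixturePair(hostLength = 2000, targetLength = 400, seed = 7)
idx <- buildHostIndex(fx$host, backend = "set")   # "bitmap" is the default
idx
#> HostIndex (set backend)
#>   k:           16
#>   sequences:   1
#>   16-mers set: 1,985

scr <- screenCandidates(idx, fx$target)
table(host_clean = scr$host_clean, composition_pass = scr$composition_pass)
#>           composition_pass
#> host_clean FALSE TRUE
#>       TRUE   279  102

pd <- designProbe(idx, fx$target)
pd
#> ProbeDesign for 'target' (400 nt target)
#>   arms (0-based [start, end)):
#>     arm_1  [  48,   68)  TAAGGTTAAGGACCCCTACC  gc=0.50 tm=51.8
#>     arm_2  [ 141,  161)  TCCCACGTTGGGCGTCAAAC  gc=0.60 tm=55.9
#>     arm_3  [ 239,  259)  CATGCTCCCTCTGCAAAGTC  gc=0.55 tm=53.8
#>     arm_4  [ 326,  346)  AAGCGTTCCCGTTCGATCGG  gc=0.60 tm=55.9
#>   probe (80 nt):  TAAGGTTAAGGACCCCTACCTCCCACGTTGGGCGTCAAACCATGCTCCCTCTGCAAAGTCAAGCGTTCCCGTTCGATCGG
#>   probe revcomp:  CCGATCGAACGGGAACGCTTGACTTTGCAGAGGGAGCATGGTTTGACGCCCAACGTGGGAGGTAGGGGTCCTTAACCTTA
#>   junctions clean: TRUE (mode all)

molesPerMicroliter(3.3, 100)
#> [1] 0.1
```

Of the 381 candidate windows all are host-clean here (the random host and
target share no 16-mer), 102 survive the composition filters, and the four
arms land near the quartile centres (positions ~50, ~150, ~250, ~350 of
400 nt). The reverse complement of the probe is what one would order and
circularise; each arm's reverse complement hybridises its target site.

The same workflow is available from a shell (see `inst/scripts/circprobe.R`):

```sh
Rscript inst/scripts/circprobe.R fixtures --host-length 2000 --target-length 400 --plants 2 --seed 5 --out-dir fx
Rscript inst/scripts/circprobe.R build-index --host fx/host.fa --out host.idx
Rscript inst/scripts/circprobe.R design --index host.idx --target fx/target.fa \
    --out design.fa --report design.tsv --candidates candidates.tsv
Rscript inst/scripts/circprobe.R quant --conc 3.3 --length 100
```

Exit codes: 0 success, 2 input/config error, 3 design failure; logs go to
standard error and end in a machine-readable `SUMMARY` line.

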