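# mtN1a

Motif-based phylogeography of mitochondrial haplogroup N1a: parsing the
HVS-I/HVS-II mutation nomenclature, subclade classification by motif
matching and near-matching, reduced median network reconstruction with
most-parsimonious tree extraction, rho-statistic coalescence dating with
Saillard standard errors, and haplotype-heterogeneity statistics — plus a
ground-truth simulator so the whole chain is testable offline.

## The scientific problem

Published human mtDNA surveys report haplotypes as control-region
*motifs* scored against the revised Cambridge reference sequence (rCRS):
`147A-172-189-223-248-320-355` lists the positions (HVS-I, minus 16000)
where a lineage differs from the reference; a trailing base marks a
transversion or recurrent derived state, `d` a deletion, `iC` an
insertion, `@` a back mutation. Pooling such surveys for haplogroup N1a
— a rare lineage prominent among the earliest central-European farmers —
requires (i) assigning every motif to the finest N1a subclade (N1a1,
N1a1a, N1a1a1, N1a1a1a, N1a1a2, N1a1a3, N1a1b) even though the
subclades are partly defined by coding-region mutations invisible in
HVS data, (ii) reconstructing the complete-genome phylogeny as a reduced
median network rooted with the rCRS as outgroup, and (iii) converting
per-clade mutation loads into ages.

For a rooted clade tree with `n` sampled mtDNAs, the coalescence-age
machinery is the rho statistic

ρ = (1/n) Σ_tips (mutations on the root→tip path),

with Saillard standard error σ² = Σ_edges (n_e/n)² m_e (n_e = mtDNAs
below the edge, m_e = mutations on it), and age = ρ·r, SE = σ·r for a
clock rate r in years per mutation — computed separately for all
coding-region substitutions and for synonymous transitions only.

The package ships the transcribed 115-row N1a survey table (166
individuals), the N1a clade-definition tree, a calibration table, and a
deterministic synthetic stand-in for the rCRS (real coordinates and gene
map, synthetic bases; see the methods vignette).

## Worked example

```r
library(mtN1a)

ref  <- rCRSAnnotation()
tree <- loadCladeTree(ref = ref)
haps <- readHaplotypeTable(system.file("extdata", "table1_n1a.tsv",
                                       package = "mtN1a"), ref)
res  <- classifyTable(haps, tree, mode = "near")
concordance(res)                       # 1
cladeCount(res, tree, "N1a1a1")        # 82  (of 166, incl. N1a1a1a)
cladeCount(res, tree, "N1a1a1a")       # 42

tab <- buildContingencyTable(haps, res, "N1a1a1a", ref = ref)
chiSquareHeterogeneity(tab)
#> Haplotype heterogeneity: n = 42; chi2 = 125.995; d.f. 81; p = 0.001
```

The classifier assigns all 166 individuals in agreement with their
recorded subclade labels; 82 of 166 fall in subcluster N1a1a1 (including
its daughter N1a1a1a, whose 42 haplotypes feed the heterogeneity test:
10 distinct HVS-I haplotypes across 10 origin groups under the shipped
grouping map, Pearson χ² = 125.995 at 81 degrees of freedom).

Dating a simulated 19-mtDNA clade (the simulator plants class-specific
Poisson mutations on a known genealogy and emits full mitogenomes):

```r
sub <- function(n, tag) paste0("(", paste0(tag, seq_len(n), ":1",
                                           collapse = ","), "):1")
nwk <- paste0("(", sub(10, "a"), ",", sub(3, "b"), ",(",
              sub(4, "c"), ",", sub(2, "d"), "):1);")   # 19 tips
cfg <- simulationConfig(seed = 19, topology = "newick", newick = nwk,
                        nTips = 19)
gt  <- simulateGenealogy(cfg, ref)
estimateAges(list(clade = gt@tree), defaultCalibrations(), ref)
#>   clade  n calibration   rho sigma ageYears ageSEYears   (excerpt)
#>   clade 19    coding.a 3.895 0.839    20019       4311
#>   clade 19       syn.c 2.895 0.779    19580       5268
```

Both clocks recover the true 23,541-year TMRCA within their standard
errors. A command-line wrapper with subcommands `classify`, `date`,
`heterogeneity` and `simulate` is installed as `exec/mtn1a`
(exit codes: 0 success, 2 usage error, 3 data error; every run writes a
`manifest.json` with input checksums).

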