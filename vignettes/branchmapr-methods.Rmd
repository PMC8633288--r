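---
title: "Methods: bulk segregant scanning, fine mapping, and downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulk segregant scanning, fine mapping, and downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchmapr)
```

# The problem

Tomato inflorescence architecture ranges from a single truss to massively
compound structures, and the number of inflorescence branches is a breeding
target. branchmapr implements the computational side of mapping a single,
partially dominant branching QTL from a biparental F2 cross between two
recombinant inbred lines: a QTL-seq style bulked segregant scan on pooled
sequencing of phenotypic extremes, interval narrowing from recombinant
progeny tests, differential-expression calling for downstream candidate-gene
work, and CArG-box promoter scanning for MADS-box (SOC1-class) binding
sites. A seeded simulator reproduces the genetic design so every stage can
be validated against known truth without any external data.

# The bulk segregant model

## SNP index and delta SNP index

Let a site segregate alleles A (from the low-branching parent) and B (from
the high-branching parent). For a sequenced bulk the *SNP index* is the
fraction of reads carrying the A allele; the *delta SNP index* is

$$\Delta = \text{index}_{\text{compound bulk}} - \text{index}_{\text{simple bulk}}.$$

Away from any trait locus both bulks are random draws from the F2 and
$E[\Delta] = 0$. Near the branching QTL, the compound bulk is enriched for
the B allele and the simple bulk for A, so $\Delta$ departs from zero — here
toward $-1$, because the high-branching allele comes from the B parent and
the index measures the A-allele fraction. Region calling uses $|\Delta|$, so
the scan itself is orientation-agnostic; the sign is reported and is a
check on the cross design.

Sites enter the scan only after retention filters: mean base quality
$\ge 20$, site quality $\ge 20$, and depth $\ge 5$. The depth rule is
applied to *both* bulks by default because an index is computed for each
(an either-bulk mode exists for sparser data). All thresholds are
inclusive.

## Sliding window

Per-site indices at 30x are noisy (binomial with n ≈ 30), so the scan
averages them in windows of 1,000 kb advancing in 10 kb steps. The
convention is concrete and testable: windows are anchored at position 1,
cover half-open intervals `[start, start + window)`, are truncated (not
dropped) at the chromosome end, and use *unweighted* arithmetic means of
the member SNPs' values. No depth weighting is applied by default — the
windowed quantity is the plain average SNP index — and empty windows carry
an explicit missing marker rather than a zero, so candidate-region runs
break there. Within-window means are computed over exactly the slice a
brute-force position filter selects, in the same order, so the
window-oracle equivalence tests can require exact equality rather than a
tolerance.

## The null threshold

No analytic null is attempted. The threshold on $|\overline{\Delta}|$ is the
$(1-\alpha)$ quantile (default $\alpha = 0.01$) of simulated QTL-free
windows. Each simulated window draws one B-allele frequency per bulk as the
mean of $2n$ Bernoulli(0.5) chromosome draws and *shares it across the
window's SNPs*, then adds binomial read noise at depths resampled from the
observed depth distribution. Sharing the frequency within a window is
deliberate: markers 10 kb apart in an F2 are nearly perfectly linked
(~0.01 recombination fraction across a whole 1 Mb window at 1.5 cM/Mb), so
the window mean inherits almost the full bulk-composition variance. A null
that drew frequencies independently per SNP would shrink the window-mean
variance roughly `n_snps`-fold and produce a threshold far too small; real
within-window linkage being marginally below 1 makes the chosen null very
slightly conservative, which the calibration tests confirm (empirical
exceedance ≈ α).

# The synthetic genetic design

The generator emulates the mapping experiment, and its defaults *are* the
study conditions:

| parameter | default | meaning |
|---|---|---|
| `chrom_length_bp` | 98 Mb | one tomato chromosome-1-like chromosome |
| `snp_spacing_bp` | 50 kb | parental SNP grid (~2,000 markers) |
| `cm_per_mb` | 1.5 | uniform genetic map scale |
| `qtl_pos_bp` | 45 Mb | seeded QTL |
| `mu_low / mu_mid / mu_high` | 4.5 / 60 / 130 | branch-count means for AA / AB / BB |
| `dispersion` | 0.2 | negative-binomial overdispersion |
| `n_f2` | 960 | population size |
| bulk thresholds | > 200, < 1.5 | branch counts defining the bulks |
| `depth_mean` | 30 | mean per-site per-bulk depth |
| `seq_error` | 0.005 | allele misassignment per read |

Crossovers are a Poisson process on the genetic map (Haldane mapping, no
interference), two independent gametes per plant. Branch counts are
negative binomial per QTL genotype class — branch numbers are overdispersed
counts, and partial dominance is encoded by the strictly intermediate
heterozygote mean (equal means are accepted as the explicit QTL-free null).
The three phenotype means and the dispersion were fixed once, from
negative-binomial tail probabilities, so that the absolute bulk thresholds
(> 200 and < 1.5 branches) select roughly 25–35 plants each out of 960 —
the design's bulk sizes — while the heterozygous class contributes
essentially nothing to either bulk. Sequencing depth per bulk is not
reported for the original experiment; 30x is a stated default, not an
inference.

What the simulator does *not* emulate: read-level artifacts (mapping bias,
indel realignment), segregation distortion, multiple or epistatic QTLs,
crossover interference, and non-uniform marker density. Passing tests
therefore demonstrate the statistical machinery under the stated design,
not robustness to those real-data complications. Multi-chromosome scans are
composed by independent per-chromosome simulations, which is exact here
because every statistic is per-chromosome.

A fraction of simulated sites (default 10%) receives a seeded defect — site
quality or base quality just below 20, or starved depth — so the retention
filters always have work whose outcome is predictable by a per-record
predicate.

# Fine mapping from recombinants

A recombinant line's progeny test classifies its (unobserved) QTL genotype:
segregating progeny imply heterozygosity, uniform high or uniform low imply
the matching homozygote (under the default partial-dominance model;
a dominant-high mode also accepts heterozygous segments for uniform-high
lines). The line then constrains the QTL to its compatible marker
segment(s). Because a breakpoint is localized only to the inter-marker gap
where the genotype changes, each segment is extended to the nearest
genotyped marker on either side and is open at those markers; beyond the
outermost markers the constraint is unbounded. The final interval is the
intersection across informative lines, reported as the tightest flanking
marker pair; an empty intersection raises an inconsistency error naming the
line at which it emptied, since under a correct single-QTL model it cannot
occur.

The logic is sound up to double crossovers inside the QTL-carrying gap
(which would make the QTL genotype invisible to both flanking markers).
At the marker densities used for validation (200 kb spacing, ~0.3 cM) that
event has probability on the order of 10^-5 per line and is ignored; this
is the same blind spot real progeny-test fine mapping has.

# Differential expression

Expression is quantified as FPKM, $10^9 c / (L N)$ for count $c$, length
$L$ bp and $N$ total mapped fragments. The between-library test is a
pooled two-proportion z-test on replicate-summed counts — an explicitly
specified statistic of the same binomial-sampling family as MA-plot-based
two-library methods, chosen over an external package's unpublished internals
so the null is fully defined and testable. P values are BH-adjusted (via
`stats::p.adjust`), and a gene is called only when all three filters pass
strictly: larger group-mean FPKM > 1, fold change > 1.5 or < 0.6666, and
adjusted p < 0.05. Fold change is computed on group-mean FPKM (the
comparison involves exactly two conditions; a configurable pseudo-FPKM,
default 0, guards ratios, and genes with both means zero are skipped).
The cross-mutant step collects per-comparison downregulated sets and keeps
genes repressed in at least `min_k = 2` comparisons.

Two caveats are intrinsic and documented rather than hidden. First, a
proportion test between libraries is sensitive to compositional shifts:
strongly changed genes perturb every other gene's library fraction. The
calibration simulator therefore seeds effects without renormalizing the
unchanged genes' expected fractions, which is the regime in which BH-FDR
control is provable; on real data with massive composition changes the test
(like the method it stands in for) inherits that bias. Second, summing
replicates treats biological replicates as technical; the test is
anticonservative under strong biological overdispersion. Published DEG
counts from the original tissue libraries are not reproducible without the
deposited raw reads, and no attempt is made to match them numerically.

# Motif scanning

Position frequency matrices are read from JASPAR text format and converted
to probabilities with a pseudocount (default 0.8, added per cell and
column-normalized). Windows score $\sum_i \log_2(p_{b_i,i}/q_{b_i})$
against a uniform background, on both strands, with reverse-strand hits
mapped to forward coordinates; the reported *relative score* is min-max
normalized over the achievable score range, and the default hit threshold
is 0.8 — the common convention for PWM calling, stated explicitly because
none is published for this locus. Windows containing N are skipped; a
consensus mode matches the degenerate CArG box `CC(A/T)6GG` exactly via
IUPAC matching. The bundled matrix is a synthetic CArG-consensus-derived
fixture (no specific public matrix accession is pinned), and S1/S2/S3-style
site positions are treated as inputs, not ground truth. Promoter offsets
are 0-based within the supplied sequence; translation-start-relative
coordinates are a declared offset away.

`deletion_effect()` reproduces the promoter-mutagenesis logic: splice out
an interval (e.g. 40 bp around the first site), rescan, and map the
after-coordinates back to the original frame; hits spanning the new
junction get a missing original coordinate because they did not exist
before.

# Orchestration and reproducibility

`run_pipeline()` drives simulate → filter → scan, finemap, deg, and motifs
stages from one YAML (or list) configuration, writes TSV/VCF/BED outputs
plus a `manifest.json` with the seed and an MD5 checksum per output, and
aborts on the first failing stage naming it. Every stochastic entry point
takes an explicit seed and restores the caller's RNG state, so identical
configurations give byte-identical outputs.

# Validation scale and known limitations

The test suite and the acceptance script run the design-scale checks at
sizes chosen to finish comfortably on one CPU: 50 replicate scans for QTL
recovery, 100 QTL-free scans against a 2,000-simulation threshold, 100
recombinant panels, 200 FDR replicates of a 300-gene matrix, and 100
seeded promoters. These sizes give Monte-Carlo standard errors small
enough for the 3-SE acceptance margins while keeping a full run in the
low minutes.

Known limitations, beyond the simulator's scope above: the scan reports
windowed means only (no G′ or kernel-smoothed statistics); candidate
regions are threshold runs, not credible intervals; fine mapping performs
no statistical interval estimation (no LOD support); and the DEG module is
not a replacement for count-model packages (DESeq2/edgeR) when replicate
overdispersion matters — it implements a specific, simple two-library
statistic faithfully.
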