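---
title: "Methods: detecting UPR activation in HD expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting UPR activation in HD expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uprhd)
```

`uprhd` asks whether the unfolded protein response (UPR) — the adaptive
program triggered by un-/misfolded protein accumulation in the ER, sensed
by IRE1 (ERN1), PERK (EIF2AK3) and ATF6 — is coordinately activated in
Huntington's disease expression data, and which genes connect it to
huntingtin. This vignette documents the statistical models, the
parameters that matter, the synthetic data the test suite runs on, and
the design choices that were genuinely open.

## Gene-set enrichment

A case/control comparison is reduced to a ranked gene list. The default
metric is signal-to-noise, $(\mu_{case}-\mu_{ctrl})/(s_{case}+s_{ctrl})$,
with each group SD floored at $0.2\,|\mu|$ of its group so that
near-constant genes cannot claim extreme scores; with fewer than 3
samples per group the metric falls back to a difference of group means on
the assumed log-like scale. Ties are broken lexicographically by symbol —
a deterministic ordering is what makes exact regression tests possible.

The enrichment score walks the ranking best-to-worst: a member of the set
("hit") at rank $i$ raises the running sum by $|s_i|^p / \sum_{hits}
|s|^p$; a miss lowers it by $1/(N-N_{hit})$. ES is the extreme deviation
of the running sum; its sign encodes whether the set gathers at the top
(up) or bottom (down). The weight exponent defaults to $p=1$, the classic
choice that balances rank position against effect magnitude; $p=0$ would
reduce to the unweighted Kolmogorov–Smirnov statistic. ES of the full
ranked universe is exactly 1, a useful invariant the tests assert.

The null is built by permutation. Phenotype permutation (relabel samples,
re-rank, rescore) preserves inter-gene correlation and is used whenever
both groups have at least 7 samples; below that the distinct label
assignments are too few, and random same-size gene sets on the fixed
ranking are scored instead. This sample-size switch mirrors the
established convention for the method. `n_perm` defaults to 1000; the
test suite and pipeline use 100–200 where only a coarse call is needed.

Normalization divides ES by the mean magnitude of same-sign null scores,
so NES is comparable across set sizes; the permutation p-value is the
add-one-smoothed same-sign tail fraction (so $p \ge 1/(n_{perm}+1)$, never
an exact zero). The empirical FDR is the ratio of the pooled null NES tail
fraction to the observed NES tail fraction, clamped to $[0,1]$ — pooled
across the (typically few) sets in a run, which is the faithful reading of
the cited procedure at small set counts. When no same-sign null value
exists the result is flagged rather than reported as NaN.

A comparison is called **up** at `fdr <= 0.05` and `NES >= +1.4`, **down**
at `fdr <= 0.05` and `NES <= -1.4`. The downregulation rule is stated in
our sources with a positive sign on the NES bound; that is internally
inconsistent (it would make every significant set "down"), so the
mirrored negative bound is implemented. The **leading edge** ("core
enrichment") is the set members at ranks up to the running-sum peak (ES >
0) or from the peak onward (ES < 0) — the genes actually driving the
signal, and the unit of all downstream intersection.

## Consensus signatures

Cross-model consensus intersects leading edges at configurable
stringency: a gene qualifies when present in every *required* comparison
(e.g. the single human comparison) and in at least `min_support` of the
optional ones. `min_support = |optional|` with no required ids is the
plain intersection; lowering it yields relaxed "at least k of n models"
signatures. The rule is monotone — shrinking `required` or lowering
`min_support` never removes a gene — and the tests assert this on random
inputs. Up- and down-signatures are built independently from up- and
down-classified comparisons; a time-series dataset contributes one
comparison per time point.

## Promoter stress-response elements

Three degenerate consensus patterns are compiled: UPRE `TGACGTGR` (8 nt,
R = G/A), ERSE-I `CCAATN{9}CCACG` (19 nt) and ERSE-II `ATTGGNCCACG`
(11 nt). Promoter windows are TSS-relative, $[-1000, +500)$ half-open,
0-based — 1500 nt, unambiguous arithmetic, with window extraction assumed
done upstream (sequences arrive pre-cut in FASTA). Scanning tests every
position on both strands by default (strandedness is a flag, since the
upstream tooling convention is not fixed); reverse-strand hits are
reported at the forward coordinate of the match start, and all
overlapping occurrences are kept. Two deliberate choices: the letter N in
a *sequence* never matches anything, even a pattern spacer — masked bases
must not create hits — and enrichment uses *presence* semantics (a gene
counts once per pattern however many hits it carries), with raw
occurrence records retained alongside since the sources are ambiguous on
this point. Matching is delegated to `Biostrings`; an independent naive
position-by-position scanner in the test suite checks equivalence on
random instances, and on uniform background the hit counts are checked
against the closed-form chance rate (for UPRE, $2 \cdot (1/4)^8$ per
strand-position).

## Enrichment statistics

The hypergeometric upper tail $P(X \ge k)$ is computed via the stable
log-space distribution function; an exhaustive binomial-coefficient
enumeration serves as the oracle for all $N \le 60$. Fisher's exact
"greater" is the same tail on cell $a$ given the margins; "two-sided"
sums the probabilities of all tables no more probable than the observed
one (with a $1+10^{-7}$ relative guard against floating-point ties,
matching the base implementation, which the tests cross-check).
Benjamini–Hochberg is the standard step-up. Over-representation analysis
runs one tail test per term over a flat term→gene map and adjusts across
tested terms; GO-graph propagation is the annotation provider's job, so a
DAG is never consumed. The default alternative is one-sided "greater"
everywhere enrichment is asked, because the scientific question is always
over-representation. For motif enrichment the universe is all promoters
supplied; target genes without a promoter record are excluded from both
sides of the table and reported, since silently keeping them would bias
the margin.

## CAG-repeat correlation

For an allelic series (default CAG lengths 20, 80, 92, 111, 140, 175 —
the ladder used in knock-in models), each gene's FPKM is Spearman-
correlated with CAG number: Pearson on mid-ranks, so ties from replicate
animals are handled exactly, and any strictly increasing transform of
either variable leaves the statistic unchanged. The empirical FDR is
estimated per tail: the CAG labels are permuted independently and
repeatedly for each gene; for a threshold $t$, $\widehat{fdr}_+(t)$ is
the mean number of null correlations $\ge t$ per round divided by the
observed count $\ge t$, clamped to $[0,1]$, and a gene's FDR is the
estimate at $t = |\rho|$, monotonized (suffix minimum over less stringent
thresholds) so FDR is non-increasing in $|\rho|$. This mean-null-tail /
observed-tail construction is the standard permutation FDR and the only
reading consistent with tail-separate FDRs being reported per gene.
Significance is `fdr < 0.01`, exposed as a flag. Replicates within a CAG
genotype are treated as independent observations. Zero-variance genes
have no defined correlation; they are excluded from observed and null
tallies and flagged. Over-representation of a gene set among the
significant genes is a one-sided Fisher test, and the expected-by-chance
overlap of a list with the genome-wide significant fraction is the plain
product, reported to one decimal.

## Network prioritization

The interactome is the 1-hop neighborhood of the six UPR core components
(ATF6, ATF4, DDIT3, EIF2AK3, ERN1, XBP1) in the supplied edge list —
depth 1 because the object of interest is "interactions of the UPR
components", not a transitive closure; depth beyond 1 is deliberately not
offered, but whether edges *among* neighbors are kept is genuinely open,
so the induced subgraph is the default with a flag to restrict to
seed-incident edges. Direct/indirect HTT-interaction types are consumed
from the input annotation, never inferred, and conflicting types are an
error. Tri-set prioritization intersects the differential-UPR consensus,
the curated therapeutic-target list and the HTT interactors, joining
motif flags and correlation statistics where available, sorted by
correlation significance. Exports are SIF and node/edge TSV; no graph
drawing.

## Identifier handling

Gene identifiers are canonicalized to upper-case symbols throughout,
because the inputs mix human, mouse, rat, worm and yeast conventions.
Ortholog maps are applied with an explicit collapse rule for many-to-one
mappings; the default keeps the source row with the largest mean
(`max-mean-probe`), the common microarray probe-collapse convention —
the sources are silent here, so this is a package convention, with
`first` and `error-on-collision` available. Unmapped identifiers are
counted and warned about, never silently dropped.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical structure* the analysis
assumes, with ground truth recorded alongside:

- `simulate_expression`: background Normal(baseline, `noise_sd`) in both
  groups, a planted set shifted by `effect * noise_sd` in cases only.
  Defaults used in the pipeline and acceptance runs: 10 vs 10 samples,
  600–1000 genes, 40–50 planted, effect 1.5–2 — a moderately powered
  microarray-scale comparison. Noise is Normal on a log-like scale with
  no heavy tails, which is sufficient because the enrichment stage
  consumes only rank structure.
- `simulate_promoters`: i.i.d. uniform A/C/G/T background — chosen
  because it makes chance-hit rates analytic for scanner calibration; a
  GC-biased background is deferred. Motifs are planted per gene at the
  configured rate, uniform offset and strand, degenerate positions
  spelled randomly.
- `simulate_cag_series`: planted genes receive a monotone shift in
  `rank(CAG)`, not raw CAG — Spearman is rank-based, so the planted truth
  is exactly monotone. FPKM is clamped at 0. The replicate count per
  genotype is a free parameter (default 4), as no canonical value exists.
- `simulate_network`: a uniform random simple graph with every seed
  guaranteed an edge, and annotation lists built to intersect the 1-hop
  interactome in exactly the planted counts, the HTT overlap nested
  inside the apoptosis overlap.

What passing tests on these data show is that the machinery is correct
and calibrated: scores match independent oracles, null p-values are
uniform, planted signals are recovered at the stated rates. What they do
not show is robustness to what real data add: probe effects, batch
structure, heavy-tailed and overdispersed counts, correlated genes,
GC-biased promoter composition, and literature-biased interactomes.

## Numerical choices and degenerate inputs

Deterministic tie-breaks everywhere (lexicographic gene order in
rankings; stable sorts in outputs); seeds are mandatory for every
stochastic stage and each pipeline stage derives its own seed from the
master seed. Add-one smoothing keeps permutation p-values off zero.
FDR ratios are clamped to $[0,1]$. Flagged-not-NaN policy: no same-sign
null (GSEA) and zero-variance genes (correlation) produce explicit
flags. Empty gene sets, malformed GMT lines, phenotype/matrix dimension
mismatches, over-full simple graphs, and missing seeds in edge lists are
immediate errors. Oracle-equivalence tests assert agreement to 1e-12;
stochastic calibration tests state their own tolerances (KS p > 0.01
over 200 repeats; null significant fraction <= 5%).

## Pipeline and configuration

`run_pipeline()` executes simulate → enrich → consensus → scan → motif
enrichment → correlate → overlay → prioritize, writing per-stage TSVs,
one log line per stage (parameters, seed, row counts) and a final
MD5 manifest; re-running a configuration reproduces every output byte
for byte, and a stage failure aborts naming the stage while retaining
completed outputs. The configuration is a flat, diffable, non-executable
document: YAML (the structured-text format with a parser available to
the package), consumed as a file or an R list; `default_config()` is the
single source of the default study conditions. Test and acceptance runs
use reduced problem sizes (200–1000 genes, 100–1000 permutations,
25–50 repeat runs) — the package's own choice of desk-scale conditions
under which the calibration and recovery properties are sharp.

## Known limitations

Two-class phenotypes only (no multi-class or continuous enrichment);
flat annotations only (no GO DAG); consensus-pattern matching only (no
PWM scoring); the permutation FDR assumes exchangeable samples under the
null (replicates treated as independent); and the headline numbers of
any real-data study depend on the upstream curation of gene sets,
promoter universes and interactomes, which this package consumes as
files and does not reproduce.
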