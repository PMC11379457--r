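---
title: "Measuring the effectiveness of selection from codon usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the effectiveness of selection from codon usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cais)
```

## The problem

Species differ in how effectively purifying selection operates: in a
population of (effective) size $N$, variants with selection coefficients
below roughly $1/N$ drift as if neutral, so larger-$N$ species can maintain
more exquisite molecular adaptation. Synonymous codon usage is a natural
readout of this "drift barrier": selection on translation speed and accuracy
weakly prefers some codons over their synonyms, and the fraction of sites
held in the preferred state depends on the product $sN$. The difficulty is
that codon usage also responds to forces that have nothing to do with
selection on codons — genome-wide nucleotide composition (mutation bias,
GC-biased gene conversion) and the amino acid composition of the proteome —
both of which vary among species. This package implements species-level
codon adaptation metrics that strip those two confounders out, plus the
simulation and comparative machinery needed to validate them and to use them
in cross-species analyses.

## The metrics

### CAIS

For a species with codon counts $N_i$ over the 64 codons (start and stop
codons included — stop codons are treated as a 21st, three-codon "amino
acid" because mammals show documented stop-codon preferences), write
$O_{i|a} = N_i / N_a$ for the usage of codon $i$ conditional on its family
$a$, and $P_a = N_a / L$ for the family marginal. Under the single-nucleotide
null model, a genome with GC content $g$ yields codon probabilities

$$p_i = \left(\frac{g}{2}\right)^{k_{GC}}
        \left(\frac{1-g}{2}\right)^{k_{AT}},\qquad k_{GC}+k_{AT}=3,$$

and within-family expectations $E_{i|a} = p_i / \sum_{j\in a} p_j$. The
Codon Adaptation Index of Species is the Kullback–Leibler divergence of
observed from GC-expected usage, re-weighted to a standardized amino acid
composition $F_a$:

$$\mathrm{CAIS} = \sum_a F_a \sum_{i\in a} O_{i|a}
  \ln\!\frac{O_{i|a}}{E_{i|a}}.$$

This is the package's default (`mode = "standard"`): a convex combination of
within-family KL divergences, hence non-negative, zero exactly when usage
sits at the GC expectation, and — because only conditional frequencies enter
— algebraically invariant to the species' own family marginals.

A second form (`mode = "literal"`) applies the re-weighting factor
$\alpha_a = F_a / P_a$ to the *global* codon frequencies,
$\sum_i \alpha_a O_i \ln(O_i / E_{i|a})$. The two differ by exactly
$\sum_a F_a \ln P_a$, which depends on the family marginals and is negative;
the literal form can therefore go below zero and is *not* invariant to amino
acid composition. Since the declared purpose of the $F_a$ re-weighting is
precisely that invariance, only the standard form achieves it, and we make
it the default while keeping the literal form available and tested. The
package never asserts which variant any particular historical analysis used.

$F_a$ defaults to the observed family frequencies of the dataset being
analyzed (`aa_frequencies()` pools a set of species; for a single species it
falls back to that species' own composition, a choice reported to make
little difference in practice). A fixed reference table can be supplied as a
TSV via `read_aa_freqs()`.

### Local-GC CAIS

GC content varies along chromosomes, mostly through GC-biased gene
conversion tracking local recombination. `build_regions()` reconstructs the
local-GC variant: every annotated CDS interval is flanked by 1500 bp on each
side (clamped at sequence ends; whether real pipelines clamp is rarely
stated, but unclamped flanks are undefined at chromosome ends), overlapping
catchments are merged — so CDS of one gene more than 3000 bp apart fall in
separate regions — and each region's $g_r$ is estimated from all of its
non-CDS sites (introns, UTRs, promoters, intergenic; ambiguous bases are
excluded from numerator and denominator, and strand is ignored because GC is
strand-symmetric). Each region's divergence $d_r$ is computed against
$E_{i|a}(g_r)$, and regions are aggregated as a codon-count-weighted
geometric mean:

$$\mathrm{CAIS}_{\mathrm{local}} =
  \exp\!\Big(\tfrac{1}{L}\sum_r L_r \ln d_r\Big),\qquad
  L = \sum_r L_r .$$

Two numerical conventions deserve note, both genuinely open choices. First,
the inner divergence uses within-region *frequencies*; an alternative
reading scales by raw counts, but only the frequency form reduces to the
whole-genome score when a single region spans the genome, and is idempotent
under region duplication — both properties are tested. Second, regions whose
inner divergence is non-positive (possible in literal mode, where the
family-entropy term is negative) have no logarithm; they are dropped from
the geometric mean and counted in the result, and an all-dropped input is an
error. Regions with no non-coding sites, or with boundary GC ($g_r \in
\{0,1\}$, where expectations degenerate), are flagged unusable and excluded,
with $L$ recomputed over the retained regions.

`gc_heterogeneity()` summarizes how much local GC departs from global GC as
the codon-count-weighted mean of $|g_r - g|$; a genome driven by gene
conversion rather than selection should score high. The alternative reading
$|\bar{g_r} - g|$ is exposed via `method = "abs_mean_dev"` without asserting
which a given analysis intends.

### CAI

The classic index is kept for comparison: $RSCU_i = N_i/(N_a/n_a)$, relative
adaptiveness $w_i = RSCU_i / \max_{j \in a} RSCU_j$, and CAI the geometric
mean of $w_i$ over all $L$ codon observations, equivalently
$\mathrm{CAI}_{raw}/\mathrm{CAI}_{max}$. Geometric means are computed as
log-sums. Codons never observed have $RSCU = 0$ and an undefined $w$; they
cannot appear in the observed product, so no pseudocount convention is
needed — but a gene scored against a reference table that lacks one of its
codons is flagged rather than silently patched.

### ENC, GC-corrected, stop codons included

For each family with $n_a \ge 2$ codons and $N_a \ge 2$ observations,

$$X_a^2 = N_a \sum_{i\in a} \frac{(O_{i|a} - E_{i|a})^2}{E_{i|a}},
\qquad
\hat F'_a = \frac{X_a^2 + N_a - n_a}{n_a\,(N_a - 1)},$$

and with $\bar F'_c$ the mean of $\hat F'$ over the families of degeneracy
class $c$:

$$\mathrm{ENC} = 2 + \frac{9}{\bar F'_2} + \frac{2}{\bar F'_3}
  + \frac{5}{\bar F'_4} + \frac{3}{\bar F'_6}.$$

Because stop codons join isoleucine as a second three-fold family, the
three-fold coefficient is 2 rather than the classic 1, and the range runs
from 21 (every family fixed on one codon) to 64 (usage at the GC
expectation), up to finite-sample noise: $\hat F'$ is an unbiased-style
correction, so with exactly uniform usage at $g = 0.5$ and $L = 10^5$ the
value lands within half a unit of 64, not exactly on it. Families observed
once ($N_a \le 1$) are excluded ($\hat F'$ is undefined at $N_a = 1$); if an
entire degeneracy class has no eligible family — only possible on tiny
inputs — its mean is imputed at the null expectation $1/n_a$ and the result
is flagged low-confidence rather than made unevaluable.

Natural logarithms are used in every KL-type term, $0 \ln 0 \equiv 0$
throughout, and no pseudocounts are ever added.

## Counting and QC

`count_codons()` counts every codon of every retained CDS record, including
the initial ATG (counted as ordinary Met — no special start handling) and
the terminal stop. Standard annotation-derived CDS FASTA files are assumed;
the default policy drops records whose length is not a multiple of 3,
records with ambiguous bases, and records with an in-frame internal stop,
and flags (but keeps) records lacking a terminal stop. Each record is
charged to its first failure only, so the QC categories and the kept count
add up to the input count. These defaults are our own conservative choice —
published pipelines rarely state theirs — and every rule can be switched off
via `qc_policy()`. Families never observed are carried as undefined (`NA`),
never imputed.

## The simulator

`simulate_genome()` provides ground truth for metric validation. Sites are
independent: each codon site is a two-allele-style fix/counter-fix process
at stationarity. The fixation probability of a new mutation in a diploid
Wright–Fisher population, $\pi(N, s) = (1 - e^{-s/2})/(1 - e^{-Ns})$, gives
the long-run odds of sitting in the deleterious state under symmetric
mutation

$$\frac{\pi(N,-s)}{\pi(N,-s) + \pi(N,s)} = \frac{1}{1 + e^{s(N - 1/2)}},$$

an identity that makes `fixation_odds()` overflow-safe at any $Ns$ (a `log`
argument returns exact log-odds where the odds themselves underflow). The
printed forms of $\pi$ in the literature differ in factors of 2; only the
odds ratio enters the simulator, and its limits — $1/2$ as $s \to 0$, $0$
as $Ns \to \infty$, strictly decreasing in between — are the tested
contract, which all consistent variants share.

For a family with more than two codons the process is extended by lumping:
mutational weights $w_i \propto (g_{\mathrm{mut}}/2)^{k_{GC}}
((1-g_{\mathrm{mut}})/2)^{k_{AT}}$ describe GC-biased mutation pressure, and
the stationary distribution is

$$P(i) \propto w_i \, e^{S_a \cdot 1[i = \text{preferred}]},
\qquad S_a = s_a (N - \tfrac12).$$

This is the unique form that (a) collapses to the two-state odds exactly for
two-fold families, (b) equals the GC-expected usage exactly at $s = 0$ for
families of any size, and (c) drives the preferred codon to fixation as
$S_a \to \infty$. A simpler rule sometimes sketched — "preferred codon with
probability $1 - \text{odds}$, remainder split by mutation bias" — violates
(b) for families with more than two codons (it would put probability $1/2$,
not $1/n_a$, on the preferred codon of a neutral four-fold family), so we
use the Boltzmann-type form above.

Simulated genomes are organized into genes (default 300 codons: forced ATG,
body drawn from the non-stop families with weights proportional to family
size, and a stop codon drawn from the STOP family's stationary
distribution), so the output passes the package's own QC untouched. The
truth table records each family's $sN$, preferred codon and stationary
frequencies, and a seed fully determines the output.

What the generator does *not* emulate: linkage and hitchhiking,
gene-conversion tracts, amino-acid composition responding to GC, expression-
weighted selection differences among genes, and within-genome GC
heterogeneity. Passing tests therefore demonstrate correctness of the
metrics under the stationary site-independent model, not that real genomes
satisfy that model.

`simulate_tree_traits()` (pure-birth trees, correlated Brownian traits via
the tree covariance Cholesky) and `simulate_trait_table()` (balanced
species × domain tables, value = domain intercept + species effect +
residual) supply fixtures for the comparative stage. Trait-table variance
components default to the scale reported for vertebrate protein disorder —
among-domain sd 0.178, residual sd 0.058 — and species effects default to
sd 0.02, chosen to match the magnitude of among-species disorder effects in
vertebrates; the trait baseline 0.3 is a typical mean disorder score.

## Comparative statistics

`species_effects()` fits `value ~ 0 + species + (1 | domain)` by REML
(lme4), so that each species' effect on the trait is estimated while domain
identity — which domains a species happens to carry — is absorbed by a
random intercept. Effects are reported sum-to-zero; the constant is
unidentified and cancels in contrasts anyway. The random term's significance
is a boundary-corrected likelihood-ratio test (halved $\chi^2_1$). Singular
or failed fits fall back to domain-centered means (exact in the noiseless
limit), and a single-domain table reduces to centered species means with a
zero domain sd. Values are fitted untransformed by default; a `transform`
argument is exposed because published analyses do not always state theirs.

`pic_correlation()` computes Felsenstein's independent contrasts (via
`ape::pic`; the contrasts' correlation, slope and $R^2$ are then taken
*through the origin*, consistent with contrasts having expectation zero
under Brownian motion). Polytomies are resolved arbitrarily into zero-length
branches offset by a small epsilon (default $10^{-8}$ of tree height);
zero-length terminal branches are an error with a suggested jitter, not a
silent patch. The through-origin contrast slope is algebraically identical
to the generalized-least-squares slope under the Brownian covariance, and
the test suite verifies this against a brute-force GLS oracle to $10^{-8}$
on random trees. `correlate_adaptation()` wires species effects and a metric
vector through the contrasts, negating ENC on request (the usual plotting
convention is $-$ENC, so that larger means more effectively selected).

## Validation design and problem sizes

The package validates itself at these scales, chosen to give comfortable
statistical resolution while keeping the full suite quick on a laptop:

* analytic zeros and invariances on exact constructed profiles
  (tolerance $10^{-12}$);
* GC-unconfounding: 50 neutral genomes of $10^5$ codons with
  $g_{\mathrm{mut}}$ uniform on $[0.3, 0.7]$ — $|r(\mathrm{CAIS}, g)| <
  0.15$, $|r(\mathrm{ENC}, g)| < 0.15$;
* selection response: $sN \in \{0.1, 1, 4, 10\}$, 20 replicates of
  $2\times10^4$ codons — mean CAIS strictly increasing, mean ENC strictly
  decreasing, with the steepest movement in the intermediate $sN$ band where
  drift and selection trade off;
* mixed-model recovery: 50 species × 200 domains at the default variance
  components, truth–estimate correlation $> 0.9$ across 10 seeds;
* end-to-end: 30 species whose $sN$ (log-uniform over $[0.1, 10]$) drives
  both their simulated genomes and their true trait effects; the
  compute → effects → contrasts pipeline recovers a positive correlation in
  at least 9 of 10 seeds.

One caveat the validation makes explicit: under the neutral stationary
model, CAI's dependence on GC is V-shaped with its maximum at $g = 0.5$
(skew in either direction lowers the geometric mean of $w$), and the curve
is nearly symmetric because two-fold and four-fold families exchange GC
roles under $g \leftrightarrow 1-g$. A linear correlation of CAI with $g$
over a *symmetric* range around 0.5 is therefore near zero even though CAI
is strongly GC-driven; over an AT-biased range such as real vertebrate
genomes ($g < 0.5$) the correlation exceeds 0.98. The test suite asserts the
V-shape and the ascending-limb correlation directly.

## Known limitations

* Only the standard nuclear genetic code is supported; the table is
  data-driven (a packaged TSV) so alternative codes can be added.
* Codon counting always uses the supplied CDS FASTA; the package does not
  splice CDS out of the genome, so region-level codon counts require CDS
  record names that match an annotation attribute (`Parent`, `ID`,
  `protein_id`, ...). A CDS whose exons span multiple regions is charged to
  the region holding most of its bases.
* The simulator's stationary independence assumptions are stated above;
  metrics applied to real genomes inherit none of them, but the validation
  evidence does.
* CAIS measures divergence from a one-parameter GC null. Forces that skew
  synonymous usage without involving selection on translation — e.g.
  dinucleotide-level mutation patterns — are not separated out; a richer
  null would require intergenic composition models beyond single-nucleotide
  frequencies.
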