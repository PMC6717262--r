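# p53resig

Sequence signatures and target-gene calling for condition-specific p53
response elements.

## The problem

The tumour suppressor p53 binds response elements (REs): ~20-bp sites made
of two 10-bp palindromic half sites, each matching the consensus
`RRRCWWGYYY` (R = purine, Y = pyrimidine, W = A/T), occasionally separated
by a short spacer. Cofactors such as iASPP reshape *which* REs p53 binds,
and the REs gained under a perturbation can carry a distinctive nucleotide
signature — for example a preference for C at position 9 and G at position
12 of the spacer-removed 20-mer, the two dyad-symmetric bases contacted by
the p53 L1 loop. `p53resig` implements the computational pipeline that
discovers and tests such signatures and calls the regulated target genes,
for analysts working downstream of ChIP-seq peak calling and RNA-seq
differential-expression quantification.

The pipeline has four stages:

1. **RE prediction.** The half-site consensus (or any user-supplied
   JASPAR-style matrix) becomes a position frequency matrix and then a
   base-2 log-odds PWM: `w(b, i) = log2[(f(b, i) + s·q(b)) / (1 + s) / q(b)]`
   with background `q` and pseudocount `s`. Every start, strand and spacer
   length in a peak is enumerated; a candidate's score is the PWM score of
   its spacer-removed 20-mer, and the highest-scored candidate per peak is
   kept (ties resolve to the smaller start, plus strand, smaller spacer).
2. **Signature statistics.** RE sets become 20 x 4 nucleotide count
   matrices and logo tables (information content `2 − H` bits per column).
   Two sets are compared per (position, base) with a two-tailed Fisher's
   exact test computed in log space, Bonferroni-corrected for the 80
   comparisons; a concurrent test handles multi-position signatures such
   as C9+G12.
3. **Integration.** Peaks whose binding signal rises more than 2-fold and
   genes with FDR < 0.05 and more than 2-fold expression change (folds on
   FPKM + 1) are intersected through a peak-to-gene assignment (gene-body
   overlap or TSS within 5 kb), yielding regulated target genes whose best
   RE is annotated with C9/G12 and the conserved CWWG-core positions.
4. **Simulation.** Seeded generators emit RE sets, peak sequences with
   embedded REs and log-normal binding signals, and expression tables with
   planted effects, so every stage is testable without external data.

## Worked example

```r
library(p53resig)

pwm <- pfm_to_pwm(build_default_pfm())
pwm
#> p53 response-element PWM (two half sites, log2 odds)
#>   source PFM : p53_half_site_consensus
#>   pseudocount: 1
#>   max score  : 13.836 bits

peak <- paste0("ACGTTGCAGTTGACCTAGCA", consensus_sequence(), "TTGACCAGCT")
best_hit_per_peak(scan_re(peak, pwm, peak_id = "demo_peak"))
#>     peak_id start strand spacer_len    score               site20
#> 1 demo_peak    20      +          0 13.83552 GGGCATGCCCGGGCATGCCC

# two RE sets at the study's scale: 208 condition-elevated REs with C9/G12
# probability 0.731, 1290 comparison REs with 0.572/0.560
x <- simulate_re_sets(208, 1290, seed = 1)
enr <- position_enrichment(count_nucleotides(x$sites_a, "iASPP"),
                           count_nucleotides(x$sites_b, "Nutlin"))
head(enr[order(enr$p), c("position","base","prop_a","prop_b","fold","p","p_bonf")], 4)
#>    position base prop_a prop_b  fold        p   p_bonf
#> 36        9    T  0.269  0.431 0.625 9.29e-06 0.000743
#> 45       12    A  0.288  0.445 0.648 2.09e-05 0.001668
#> 47       12    G  0.707  0.550 1.284 2.15e-05 0.001722
#> 34        9    C  0.716  0.566 1.266 3.88e-05 0.003103
```

The scanner reports the planted consensus at offset 20 with the maximal
score (13.84 bits). In the enrichment table only positions 9 and 12 fall
below the Bonferroni threshold: C is enriched at 9 (71.6% vs 56.6%, fold
1.27) and G at 12 (fold 1.28), with the complementary depletions of T9 and
A12 — exactly the planted signature, at folds close to the published
1.28/1.31. Proportions `prop_a`/`prop_b` are fractions of each RE set;
`fold` is their ratio; `p_bonf = min(1, 80p)`.

The same machinery drives the integration stage:

```r
scen <- simulate_iptg_scenario(seed = 95)
de  <- filter_de_genes(scen$de)                       # 475 genes (194 up, 281 down)
dp  <- call_differential_peaks(scen$peaks)            # 12 peaks above 2-fold
asg <- assign_peaks_to_genes(scen$peaks, scen$models)
ip  <- call_iptgs(de, dp, asg, scan_peaks(scen$sequences, pwm))
nrow(ip); sum(ip$concurrent_c9_g12)
#> [1] 13
#> [1] 9
```

Thirteen target-gene records arise from 12 differential peaks (one peak
sits in two overlapping gene bodies), and 9 of the 12 REs carry both C9
and G12.

A thin command-line front end with subcommands `scan`, `logo`, `enrich`,
`integrate`, `simulate` and `run-all` is installed under
`system.file("scripts", "p53resig", package = "p53resig")`.

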