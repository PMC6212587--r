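# ribopert

Quantifying how perturbations in translation-elongation factors change
protein synthesis rate, by exact stochastic simulation of ribosome
traffic.

Changes in tRNA pools, elongation factors, or local mRNA structure alter
the speed at which ribosomes decode individual codons. Whether such a
change actually moves a gene's protein output depends on where the
perturbed codon sits and on how initiation-limited the mRNA is. ribopert
is for researchers in systems and synthetic biology who want to ask that
question quantitatively: it simulates translation as a TASEP (totally
asymmetric simple exclusion process) with extended ribosomes and
codon-specific rates, calibrates per-gene initiation rates against
ribosome-density measurements, and measures translation-rate sensitivity
to single-codon, multi-codon and codon-type-global perturbations.

## The model in brief

Ribosomes of footprint $s = 9$ codons hop 5′→3′ over the $n$ sense
codons of an ORF with exponential waiting times — rate $\lambda_i$ at
codon $i$ — without overlapping; initiation fires at rate $\lambda_0$
only while the first $s$ codons are clear. The translation rate TR is
the steady-state termination flux. For a perturbation $\theta$ that
rescales targeted rates by $1+p$ (and $\lambda_0$ by $\alpha$), the
sensitivity is

$$\mathrm{sensitivity}(\theta) =
\frac{\langle TR(\theta(\lambda_0, \lambda))\rangle -
      \langle TR(\lambda_0, \lambda)\rangle}
     {\langle TR(\lambda_0, \lambda)\rangle},$$

estimated from replicate pairs on common random streams. Evaluated one
codon position at a time this gives the sensitivity profile
$SP(i, p, \alpha)$; its mean over codons 1–9 ("start-region
sensitivity") is governed by $\xi = \lambda_0/\langle\lambda_i\rangle$,
with three regimes: rising with $\xi$ (regime 1, $\xi \lesssim 0.1$),
falling (regime 2, $0.1 \lesssim \xi \lesssim 0.5$), and saturated near
zero (regime 3). A codon-order permutation test
(`permute_codons()` / `pi_matrix()`) asks whether profile structure is
attributable to codon placement rather than composition, with Bonferroni
control over all region pairs $a \le b \le 200$.

## Worked example

A two-codon gene with unit rates and single-site footprint is small
enough to solve exactly — its chain has four states and stationary flux
2/5 — and the simulator must agree:

```r
library(ribopert)
g <- gene_model("tiny", rates = c(1, 1), init_rate = 1, footprint = 1)
exact_small_lattice_rate(g)
#> [1] 0.4
simulate_tasep(g, sim_config(seed = 7, replicates = 8,
                             measure_terminations = 5000))
#> <sim_result 'tiny'>
#>   TR = 0.3978 /s (sd 0.00446, 95% CI half-width 0.00373, 8 replicates)
#>   mean bound ribosomes = 1.006; 40000 terminations over 1.006e+05 s
```

The headline analysis maps start-region sensitivity against $\xi$ for
the default synthetic gene (500 codons, all rates 1, so $\xi$ equals the
initiation rate), at a −50% single-codon perturbation (a few minutes on
one CPU):

```r
scan <- regime_scan(config = sim_config(seed = 5, replicates = 10,
                                        measure_terminations = 2000))
transform(scan, percent = round(100 * start_sensitivity, 2))
#>     xi start_sensitivity           se percent
#> 1 0.02      -0.013475930 0.0006059286   -1.35
#> 2 0.05      -0.030519184 0.0006942071   -3.05
#> 3 0.08      -0.038981650 0.0006306631   -3.90
#> 4 0.10      -0.041303409 0.0005841582   -4.13
#> 5 0.12      -0.041091617 0.0006793096   -4.11
#> 6 0.15      -0.036954217 0.0005625720   -3.70
#> 7 0.20      -0.029022870 0.0004271319   -2.90
#> 8 0.30      -0.007625691 0.0003142504   -0.76
```

Halving one of the first nine decoding rates costs this gene up to ~4%
of its protein output, with the worst case at $\xi \approx 0.1$ — the
regime-1/regime-2 boundary. Positional structure at low $\xi$ shows the
footprint directly: codons 1–9 carry ~3% sensitivity each, and the
profile drops sharply at codon 10, where a delayed ribosome no longer
blocks initiation:

```r
gene <- make_uniform_gene(n = 500, lambda0 = 0.05)
sp <- sensitivity_profile(gene, p = "-50%", positions = 1:30,
                          config = sim_config(seed = 11, replicates = 20,
                                              measure_terminations = 2000))
leading_sensitive_block(sp)
#> [1] 9
```

`run_pipeline()` chains the stages (synthetic cohort → density targets →
initiation-rate calibration → profiles and per-gene summaries → optional
codon-order test) from a YAML or list configuration and writes
checksummed TSVs.

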