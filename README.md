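# pleiotree

Pleiotropy-informed prioritization of GWAS SNPs with functional-annotation
trees.

## What problem it addresses

Genome-wide association studies report, per SNP, an association p-value for
a trait. Two persistent difficulties are (i) limited power to detect the
many variants with small effects, and (ii) the lack of a functional
explanation for hits, most of which fall in non-coding regions. When two
traits share genetic architecture (pleiotropy), analysing their summary
statistics jointly — and letting binary functional annotations (e.g.
thresholded tissue-specific regulatory scores) inform the prior — improves
both power and interpretability.

`pleiotree` is for statistical geneticists who have, for M SNPs, p-values
for two traits and K binary annotations, and who want (a) per-SNP local
false discovery rates for association with trait 1, trait 2, and both
traits jointly, with global FDR control, and (b) an interpretable decision
tree showing which *combinations* of annotations (intersections, unions,
complements) characterize the risk-associated SNPs.

## The model

Each SNP i carries a latent state over the two traits,
Z\_i ∈ {00, 10, 01, 11} (null/null, trait-1 only, trait-2 only, both).
Conditional on the state, p-values are independent with

* Y\_id | null ~ U\[0, 1\]
* Y\_id | non-null ~ Beta(α\_d, 1), 0 < α\_d < 1 (density α y^(α−1),
  concentrated near 0),

and the prior state probabilities are a function of the annotation vector:
π\_il = P(Z\_il = 1 | a\_i1, …, a\_iK) = f(a\_i1, …, a\_iK).

Fitting is a two-stage EM algorithm:

1. **Stage 1** estimates (α₁, α₂) with closed-form weighted-MLE updates,
   while f is a multivariate linear regression of the four responsibility
   columns on the annotations (fitted values → priors).
2. **Stage 2** fixes the α's and replaces the linear M-step with a
   multivariate regression tree grown on the responsibilities and pruned at
   a complexity parameter cp (a split survives only if it reduces total
   deviance by more than cp × root deviance per split). Because the tree
   step does not maximize the EM objective, Stage 2 is a *generalized* EM:
   iterations that fail to increase the incomplete log-likelihood are
   discarded and the previous state is restored.

Inference uses the posterior responsibilities z\_il:
fdr1 = z00 + z01, fdr2 = z00 + z10, fdr12 = z00 + z10 + z01, and the
direct posterior probability procedure declares the largest
ascending-lfdr prefix whose mean lfdr stays at or below the nominal global
FDR level. The pruned tree's splits name the annotations (and their
combinations, via root-to-leaf paths) that drive the priors.

## Worked example

```r
library(pleiotree)

# simulate the reference design: M = 10,000 SNPs, K = 25 annotations,
# risk SNPs defined by L1 = A1&A2 (trait 1), L2 = A3&A4 (trait 2),
# L3 = A5&A6 (both), 10% annotation density, 50% pair overlap
sim <- simulate_pleio(sim_config(seed = 11))
fit <- pleiotree(sim$pvals, sim$annotations)
fit
#> Pleiotropy-informed annotation-tree mixture fit
#>   SNPs: 10000   annotations: 25
#>   alpha1 = 0.4253, alpha2 = 0.4197
#>   incomplete log-likelihood: 1198.428
#>   selected annotations: A1, A2, A3, A4, A5, A6
```

The α estimates are close to the generative value 0.4, and the converged
tree uses exactly the six causal annotations — none of the 19 noise
annotations. Association calls at a nominal global FDR of 5%:

```r
tab <- assoc(fit, level = 0.05)
summarize_associations(tab)[1:3]
#> $n_marginal_trait1
#> [1] 1039
#> $n_marginal_trait2
#> [1] 1045
#> $n_joint
#> [1] 523
```

About 1,000 SNPs are truly associated with each trait (500 marginal + 500
joint) and 500 jointly; the counts above are the SNPs declared at 5% FDR.
Truth-based performance of the fit:

```r
evaluate_fit(sim, fit, level = 0.20)[c("auc12", "power12", "fdp12")]
#>   auc12 power12 fdp12
#> 1     1       1   0.2
```

`print(fit$tree)` shows the fitted tree with leaf-wise prior state
probabilities; `tree_combinations(fit)` lists the root-to-leaf annotation
combinations.

A thin command-line front end with `fit`, `assoc`, `simulate`, `evaluate`
and `replicate` subcommands is installed at
`system.file("cli", "pleiotree.R", package = "pleiotree")`.

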