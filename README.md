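# modconn

Modular decomposition of the variability of connectivity matrices.

Studies of brain functional connectivity summarize each subject (or time
window) as a symmetric D × D matrix of pairwise signal correlations
between D regions. Given a stack of N such matrices, the question is how
connectivity varies across the collection. The classical answer is PCA on
the vectorized matrices: each component is a unit-norm *eigenconnectivity*
matrix **B** maximizing the variance of the scores
s_n = tr[**B**ᵀ X̃_n] over the centered matrices X̃_n — but at realistic D
the unconstrained **B** is diffuse and hard to interpret.

`modconn` implements a constrained PCA in which every eigenconnectivity is
factorized through network modules:

    B = W G Wᵀ,   W ∈ Ω₊ (disjoint, nonnegative columns), ‖w_k‖ = 1, ‖G‖ = 1

The D × K weight matrix **W** defines K disjoint modules with nonnegative
node weights; the small symmetric K × K matrix **G** holds the module-level
eigenconnectivity — diagonal entries are intra-module variability,
off-diagonal entries inter-module variability. Disjointness plus unit
columns give WᵀW = I, so the constrained problem is still a PCA problem; it
is solved by alternating an auxiliary-variable bound with a single
projected-gradient ascent step on the Stiefel manifold per iteration,
initialized by a stepwise spectral-rotation factorization of the PCA
eigenconnectivity. The package also provides the two reference methods the
modular solver is compared against — unconstrained PCA with deflation, and
the rank-two orthogonal factorization B = (w₁w₂ᵀ + w₂w₁ᵀ)/√2 that models
inter-module variability only — plus simulation generators with planted
ground truth, a recovery benchmark, adjusted explained variance for
non-orthogonal component sets, and graph/spatial exports of fitted modules.

For who: anyone decomposing collections of symmetric association matrices —
functional connectivity across subjects or sliding windows, but nothing in
the method is specific to correlations or to brains.

## Worked example

Simulate 2000 connectivity matrices (20 nodes) around one planted modular
component in the hard regime where intra-module variability dominates
(c = 0.6), and fit one modular component with K = 2:

```r
library(modconn)

sim <- simulate_modular_component(c = 0.6, N = 2000, seed = 1)
cs  <- center_stack(sim$stack)

fit <- mcf_fit(cs, K = 2, M = 1, config = solver_config(seed = 1))
fit$components[[1]]
#> <mcf_component> K = 2 modules, objective 2399.93, converged after 6 iterations
#>   module sizes: 9, 8

round(fit$components[[1]]$G, 3)
#>         module1 module2
#> module1   0.544   0.455
#> module2   0.455   0.538
```

The planted G has diagonal √(0.6/2) ≈ 0.548 and off-diagonal
√(0.4/2) ≈ 0.447; the fit recovers both to two digits, and the module
sizes 9 and 8 are the planted node sets {4…8} and {12…18} plus a few
noise nodes carrying weights an order of magnitude smaller (`tidy(fit)`
lists them: planted nodes weigh ≈ 0.45, spurious ones ≈ 0.02). The
sign-aligned recovery errors ‖B − B̂‖ show why the modular constraint
matters in this regime — the rank-two baseline cannot represent
intra-module variability at all:

```r
estimation_error(sim$truth$B_true[[1]], fit$components[[1]]$B)
#> [1] 0.06093939
ocf <- ocf_fit_component(cs, solver_config(seed = 1))
estimation_error(sim$truth$B_true[[1]], ocf$B)
#> [1] 0.7718139
```

A command-line wrapper with `simulate | fit | stepwise | spectrum |
benchmark | export` subcommands is installed at
`system.file("cli", "mcf-tool.R", package = "modconn")`.

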