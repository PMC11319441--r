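# chromcore

Chromatin interaction networks reorganize when cells change state. A
striking example is oncogene-induced senescence (OIS): chromatin architect
proteins such as HMGA1 relocate, long-range contacts are gained and lost en
masse, and the *gained*-contact network condenses into a small, densely
interconnected core of genomic bins whose genes are coherently repressed,
while bins that *lose* contacts to that core tend to be activated.
Knockdown of the architect protein reverses the rewiring.

`chromcore` is an R package for quantifying exactly this kind of
reorganization. Given binding peaks, differential chromatin-interaction
tables between conditions, contact matrices and differential expression, it:

* calls **dense binding regions** from rolling peak density with an
  automatic knee threshold;
* builds per-chromosome **differential interaction networks** and computes
  the exact **k-core decomposition** of the gained network (linear-time
  bucket peeling);
* assigns every network bin to one of five connectivity classes —
  **Core** (deep in the gained k-core), **AltCore** (a dense cluster
  detached from the Core), **Peri** (gained edges onto the Core),
  **ExCore** (lost edges to the Core), **Other**;
* derives **A/B compartment scores** (coverage masking → ICE balancing →
  distance-corrected observed/expected → correlation PCA, sign-oriented
  against a reference track);
* **integrates** the classes with expression, compartments, binding and
  interaction strength;
* ships a **synthetic data generator** with planted truth and a
  deterministic end-to-end **pipeline** with manifest, checksums and event
  log.

All coordinates are 0-based half-open; all writers emit LF-only,
full-precision text, so identical configurations produce byte-identical
outputs.

See `vignettes/chromcore-methods.Rmd` for the methods and the reasoning
behind the numerical choices.

## Worked example

Simulate a dataset with planted structure, build the gained network,
decompose it and classify bins — every number below is real output:

```r
library(chromcore)

spec <- synthetic_spec(seed = 42, noise_p = 0.02)   # 3 chromosomes, 200 kb bins
dn   <- simulate_diffnet(spec)                      # two contrasts + truth
nets <- build_networks(dn$tables[[1]])              # per-chromosome graphs

dec <- kcore_decompose(nets[["chrA"]])
table(core = dec$core_number)
#> core
#>  0  1  2  4  7
#> 17 48 39  5  8

table(tier = dec$tier)
#> tier
#>    low medium   high
#>    104      5      8
```

The planted 8-bin Core clique surfaces as the k-max = 7 core; the detached
5-bin AltCore clique sits at core number 4. Classifying all bins across the
three chromosomes:

```r
labels <- classify_all(nets, lapply(nets, kcore_decompose))
table(labels$label)
#>    Core    Peri AltCore  ExCore   Other
#>      24      31      15      50     238
```

All 57 planted bins (24 Core, 9 Peri, 15 AltCore, 9 ExCore) are recovered
exactly; the surplus Peri/ExCore counts are random noise bins that acquired
a single qualifying edge to the Core, which is what those classes mean.

Dense binding regions recover the planted 2 Mb enriched intervals:

```r
pk <- simulate_peaks(spec)
ds <- call_dense_regions(pk$peaks, spec_layout(spec))
ds$threshold
#> [1] 76
ds$regions[, c("chrom", "start", "end", "n_windows", "max_count")]
#>   chrom   start      end n_windows max_count
#> 1  chrA 9970000 12020000       389       124
#> 2  chrB 9965000 12035000       393       127
#> 3  chrC 9975000 12020000       390       120
interval_jaccard(ds$regions, pk$truth)
#> [1] 0.973236
```

## Acceptance metrics

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

recomputes the headline quantities from fresh simulations (k-core agreement
with an independent implementation, planted-class recovery with and without
noise, dense-region Jaccard, ICE diagnostics, compartment sign agreement,
integration sign consistency, pipeline determinism) and writes them as a
flat JSON object. All randomness derives from `--seed`.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "chromcore", load_package = "installed")'
```

The suite includes brute-force oracles (independent k-core peeler,
eigen-decomposition oracle for compartment scoring), property tests
(monotonicity of dense-region calling, core-hierarchy nesting, ICE
scale-invariance) and planted-recovery acceptance tests.
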