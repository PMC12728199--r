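# akigraph

Early prediction of acute kidney injury (AKI) from hourly ICU physiological
time series, for methods researchers working on graph-based clinical risk
models and decentralized (privacy-preserving) training.

AKI is labeled from serum-creatinine dynamics by the KDIGO rule — a rise of
≥ 0.3 mg/dL within 48 h of any earlier value, or ≥ 1.5 × baseline within
7 days of admission (baseline = first observed creatinine, or an MDRD
back-calculation at eGFR 75 mL/min/1.73 m² when that value is untrusted).
The package predicts, 6–12 h ahead, whether that rule is about to fire, from
twelve routine variables: creatinine, SBP, DBP, MAP, HR, Temp, Resp,
lactate, O2Sat, BUN, pH, WBC.

## The models

**Patient-specific feature graphs.** For each patient a pre-prediction
window (default 48 h) is turned into a graph: nodes are the 12 features,
edges carry the signed Pearson correlation *w<sub>ij</sub>* of the two
feature series whenever |*r*| > 0.30, and each node holds short temporal
feature vectors *h*<sub>i,t</sub> = [x<sub>i,t</sub>, x<sub>i,t−1</sub>,
x<sub>i,t−2</sub>].

**Centralized GAT.** A two-layer multi-head graph-attention network:
per head *k*, scores
*e<sub>ij</sub> = LeakyReLU(a<sup>k</sup> · [W<sup>k</sup>h<sub>i</sub> ‖ W<sup>k</sup>h<sub>j</sub>])*
are softmax-normalized over the neighborhood into coefficients
*α<sub>ij</sub>*, and node updates are
*h′<sub>i</sub> = ReLU(Σ<sub>j</sub> α<sub>ij</sub> W<sup>k</sup>h<sub>j</sub>)*.
Layer 1 concatenates K = 8 heads of width 64 (512 dims), layer 2 averages
its heads; global mean pooling over nodes and time feeds a sigmoid output
*P<sub>AKI</sub> = σ(W<sub>fc</sub> h<sub>global</sub> + b)*. Training:
Adam, lr 0.001, cross-entropy, 50 epochs, batch 128, dropout 0.3.

**GL-AA-GAT (gossip learning with adaptive aggregation).** Five nodes hold
disjoint shards; each round every node trains one local epoch and exchanges
parameters with a random peer (element-wise averaging); optional task
scheduling orders exchanges by local validation accuracy. After 18 rounds a
global model is built by adaptive aggregation —
*θ<sub>global</sub> = Σ<sub>n</sub> p<sub>n</sub> θ<sub>n</sub>* with
*p<sub>n</sub> = exp(acc<sub>n</sub>)/Σ<sub>m</sub> exp(acc<sub>m</sub>)* —
distributed back and fine-tuned locally at η = 1e-4. A FedAvg baseline and
a communication ledger (27 MB payload ⇒ 135 MB/round FedAvg vs 27 MB/round
gossip) complete the comparison.

A synthetic ICU cohort generator (Gaussian-copula AR(1) vitals with
physiological correlation blocks, planted pre-onset lactate/MAP/HR drift and
creatinine rise, KDIGO-consistent labels) and a full evaluation battery
(confusion metrics, MCC, AUROC/AUPRC, Brier, log loss, DeLong, chi-square,
Hosmer–Lemeshow, decision-curve analysis, attention-based feature
importance) make the whole pipeline testable end-to-end without external
data.

## Worked example

```r
library(akigraph)

## 600-patient synthetic cohort at 15% AKI prevalence
cohort <- generateCohort(cohortConfig(nPatients = 600, seed = 42))
mean(akiLabels(cohort))
#> [1] 0.175

## stratified 85:15 split, z-scoring by training statistics
sp   <- splitCohort(cohort, 0.85, seed = 1)
zs   <- zscoreNormalize(sp$train)
test <- zscoreNormalize(sp$test, zs$stats)$cohort

## 24-hour windows -> feature graphs
spec   <- windowSpec(windowHours = 24)
gTrain <- buildGraphs(zs$cohort, spec, seed = 2)
gTest  <- buildGraphs(test, spec, seed = 3)

## a reduced GAT for a quick run
fit <- trainCentralized(
  gTrain, NULL,
  gatConfig(d0 = 3, dh = 16, heads = 2, dropout = 0.2),
  trainConfig(lr = 0.003, epochs = 10, batchSize = 64, seed = 5)
)
preds <- predictionSet(sapply(gTest, graphLabel),
                       gatPredict(fit$model, gTest), "central")
round(unlist(metricReport(preds)[c("accuracy", "auroc", "auprc", "brier")]), 3)
#> accuracy    auroc    auprc    brier
#>    0.822    0.703    0.349    0.141
```

`accuracy` is the fraction correct at the 0.5 threshold (against this
split's ~0.82 negative base rate), `auroc` the probability a random
AKI-positive window outranks a negative one, `auprc` the step-integrated
precision-recall area (base rate ≈ 0.18), and `brier` the mean squared
probability error. This is a deliberately quick run — ten epochs of a
width-16 model on 600 patients; longer training at larger width (see the
methods vignette) raises the held-out AUROC into the mid 0.8s on this
generator. The decentralized protocol runs the same architecture over five
nodes:

```r
shards <- lapply(splitCohort(cohort, 0.85, nNodes = 5, seed = 1)$shards,
  function(s) {
    g <- buildGraphs(zscoreNormalize(s, zs$stats)$cohort, spec, seed = 4)
    v <- seq_len(round(0.15 * length(g)))
    list(train = g[-v], val = g[v])
  })
run <- runGossip(shards,
                 gatConfig(d0 = 3, dh = 16, heads = 2, dropout = 0.2),
                 trainConfig(lr = 0.003, batchSize = 64, seed = 5),
                 gossipConfig(nNodes = 5, rounds = 18, seed = 7))
auroc(predictionSet(sapply(gTest, graphLabel),
                    gatPredict(run$model, gTest), "gossip"))
#> [1] 0.558277
totalBytes(run$ledger) / 1e6   # MB moved over 18 gossip rounds
#> [1] 0.124488
```

(At this toy scale — ~100 training graphs per node — 18 gossip rounds are
far from convergence; the acceptance-scale study in
`scripts/acceptance.R` runs 2,000 patients.)

A thin command-line front end over these functions lives at
`inst/cli/akigraph.R` (subcommands `simulate`, `build-graphs`,
`train-central`, `train-gossip`, `train-fedavg`, `evaluate`, `compare`,
`sweep`), each run writing a JSON manifest for reproducibility.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "akigraph",
                               load_package = "installed")'
```

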