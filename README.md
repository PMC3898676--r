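# pherocircuit

Matching neuron morphology to physiology in identified cell classes of
the fly olfactory system — and anywhere else one has registered neuron
tracings plus trial-structured intracellular recordings.

The package is aimed at the analysis that sits between raw data and a
figure: given SWC reconstructions registered to a common template and
current-clamp odor/stimulation trials, it answers *do these neurons fall
into morphological groups, and do those groups respond differently?*

## What it computes

**Morphology.** Each skeleton is reduced to a dot-property cloud (points
with unit tangent vectors). A query neuron *Q* is scored against a
target *T* by

    S(Q,T) = (1/n) Σᵢ |qᵢ · tⱼ| · exp(−dᵢⱼ² / 2σ²),

the mean over query points of the absolute tangent dot product with the
nearest target point, Gaussian-weighted in distance (σ = 3 μm by
default). Scores run from 1 (identical) to 0; distances `1 − S` are
symmetrized and clustered with Ward linkage, and dendrogram cuts give
morphological groups.

**Physiology.** Spikes are extracted by thresholding the second
derivative of a binomially smoothed trace; odor responses are spike
counts in a 500 ms window starting 150 ms after valve opening, control
subtracted, tested with the exact one-sided two-sample Poisson test and
Benjamini–Hochberg FDR (significant at adjusted p < 0.01). Tuning
sharpness is lifetime sparseness in [0, 1]. Subthreshold responses
(45 ms boxcar, peak over baseline) are tested by permutation against
pseudo responses measured in pre-stimulus windows. For direct
glomerular stimulation, the sustained artifact (~1 mV/V) is fitted and
subtracted, and synaptic latency is the earliest 0.5 ms bin from which
the test trace stays significantly above control (one-tailed rank-sum,
p < 0.05) through the end of the pulse.

**Synthetic data.** Seeded generators produce skeleton populations with
group-specific dendrite placement and recordings with the assumed noise,
latency and rate structure, so the whole pipeline is testable and
calibratable without any raw-data download.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic
data; each writes its tables under `results/`. For instance:

```sh
Rscript analysis/01_simulate_morphology.R
Rscript analysis/02_cluster_morphology.R
```

prints

    Simulated 20 skeletons in 2 groups -> results/morphology
    Mean cable length: 483.7 um
    Cluster x true-group contingency:
         A  B
      1 10  0
      2  0 10
    Perfect recovery: TRUE

i.e. Ward clustering of the pairwise similarity scores recovers the two
simulated dendritic-placement groups exactly. The physiology steps
behave the same way:

```sh
Rscript analysis/04_subthreshold_responses.R
Rscript analysis/05_stimulation_latency.R
```

    cell_id        peak_depolarization  raw_p        adjusted_p   significant
    input_cell     5.37                 0.0020       0.0020       TRUE
    no_input_cell  0.06                 0.9394       0.9394       FALSE

    Fitted artifact gain: 1.00 +/- 0.00 mV/V (true 1)
    Evoked depolarization: 10.0 +/- 0.0 mV
    Latency: 1.85 +/- 0.29 ms (true 2.0)

The cell with an 8 mV odor-locked EPSP is declared significant against
its pseudo-response null (the 45 ms boxcar attenuates the transient peak
to ~5.4 mV); the no-input cell is not. The latency estimator recovers a
2 ms synaptic delay to within one 0.5 ms bin on average, after removing
a 3 mV sustained stimulation artifact.

In R, the same machinery is a few calls:

```r
library(pherocircuit)
pop <- simulate_skeleton_population(morpho_population_spec(seed = 1))
dps <- lapply(pop$skeletons, function(s)
  to_dotprops(resample_skeleton(s, 1), k_neighbors = 5))
tree <- cluster_neurons(distance_matrix(dps, similarity_params(sigma = 3)))
cut_clusters(tree, k = 2)
```

`run_pipeline()` (script `06`) composes everything — simulation,
clustering, spike detection, response testing, sparseness — into one
deterministic run whose summary table is ordered by dendrogram leaf
order, and logs every constant it used.

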