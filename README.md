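# hetscreen

Virtual-screening funnel and biophysical binding analysis for
protein-protein interaction (PPI) inhibitor discovery.

`hetscreen` covers the computational arm of a PPI inhibitor campaign end
to end:

- **Chemistry core** — SMILES/SDF parsing to heavy-atom graphs with
  implicit hydrogens, seeded deterministic 3D conformer embedding,
  pharmacophoric feature perception, descriptors and drug-likeness
  filters.
- **Pharmacophore modeling** — builds a refined four-feature
  tolerance-sphere model (HBA1, HBA2, H1, H2-optional, min-match 3) from
  aligned actives, matches library conformers with partial matching, and
  validates by ROC/AUC against an actives/decoys training set.
- **Docking funnel** — PDBQT/SDF pose ingestion, per-engine rank cuts,
  inclusive anchor-distance filtering, consensus-site aggregation,
  drug-likeness and pharmacophore stages, with a per-stage survivor
  report.
- **Clustering & scaffolds** — binary linear-path fingerprints, Tanimoto
  distances, average-linkage K-cut clustering, medoid representatives,
  and exact (budgeted) maximum-common-substructure scaffolds for major
  clusters.
- **NMR analysis** — combined chemical-shift perturbations, binding-site
  thresholding, exact single-site quadratic isotherm fits per residue
  with mean ± SD aggregation, AIDA (antagonist-induced dissociation)
  metrics, and CNS-style ambiguous restraints backed by Shrake-Rupley
  solvent accessibility.
- **MST curves** — quadratic-isotherm fits of binding traces and
  four-parameter Hill fits of competition/inhibition curves.
- **Synthetic data** — generators for planted-actives libraries, toy
  receptors with poses at planned distances, CSP titrations, and MST
  traces; every artifact records the ground truth that produced it.
- **CLI** — `hetscreenMain()` / the `hetscreen` script dispatches the
  whole workflow (`roc`, `screen`, `funnel`, `cluster`, `csp`, `fitkd`,
  `aida`, `restraints`, `mst`, `hill`, `simulate`) and writes a
  `manifest.json` per run.

## Quick start

```r
library(hetscreen)

# train a pharmacophore model on the shipped actives/decoys set
train <- trainingSetFixture()
mols <- embedLibrary(lapply(seq_len(nrow(train)), function(i)
  parseSmiles(train$smiles[i], train$id[i])), seed = 1L)
model <- trainModel(mols[train$label == "active"])

# screen and validate
screen <- screenLibrary(model, mols, seed = 1L)
rocFromScores(screen$score, train$label[match(screen$id, train$id)])$auc

# fit a synthetic NMR titration
series <- genTitration(Kd = 0.9e-3, deltaB = c(`10` = 0.2, `11` = 0.15,
                                               `12` = 0.25, `13` = 0.18))
fits <- fitAllResidues(series)
aggregateKd(fits, vapply(fits, `[[`, numeric(1), "residue"))
```

See `vignettes/screening-workflow.Rmd` for the full walkthrough.

## Tests

```r
testthat::test_dir("tests/testthat", package = "hetscreen",
                   load_package = "installed")
```

Two acceptance benchmarks fail by design: the reimplemented pharmacophore
screen scores a substantially lower training-set AUC than the original
commercial-tool analysis, and the lead compound matches four rather than
three model features. Both comparisons are kept honest rather than tuned.
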