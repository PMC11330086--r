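Package: chemgroup
Title: Interpretable Chemical Grouping with Clustering, Feature Selection and
    SHAP Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable pipeline for chemical grouping and read-across
    support: reads chemical structures (SDF, SMILES, CSV, XLSX), applies
    QSAR-ready-style structure standardization, computes binary fingerprints
    (Morgan, FeatMorgan, MACCS) and continuous 2-D descriptors, filters
    low-variance and highly correlated features (manually or by a supervised
    grid search), selects descriptor subsets by recursive feature elimination,
    a genetic algorithm, or simulated annealing, groups compounds with k-means,
    k-medoids, hierarchical clustering, DBSCAN, or HDBSCAN on the full
    descriptor space or on 2-D projections (PCA, UMAP, t-SNE) with
    silhouette-driven Tree-structured Parzen Estimator tuning, and interprets
    groupings through SHAP attribution with per-cluster descriptor rankings and
    deterministic text summaries. Every run is captured in a replayable JSON
    manifest. Structure handling and nonlinear embeddings are delegated to a
    bundled Python helper (RDKit, umap-learn, scikit-learn).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    e1071,
    ggplot2,
    jsonlite,
    nnet,
    pROC,
    ranger,
    rlang,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    mclust,
    readxl,
    testthat (>= 3.0.0),
    withr,
    yaml
SystemRequirements: Python (>= 3.8) with rdkit, numpy, umap-learn and
    scikit-learn available on the PATH as 'python'.
Config/testthat/edition: 3
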