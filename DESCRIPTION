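Package: rxrec
Title: Drug Recommendation from Diagnosis Codes by Classification,
    Collective Matrix Factorization, and Hybrid Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying visit-level drug recommendation from
    electronic health records. Generates synthetic outpatient cohorts of
    elderly patients with diabetes, hypertension and dyslipidemia with a
    planted prescription model; prepares frequency-filtered indicator
    matrices with therapeutic drug grouping and patient-disjoint splits;
    fits one-vs-rest probabilistic classifiers (nearest neighbours,
    ridge-penalized logistic regression, random forests, multilayer
    perceptron) and bias/latent-factor recommenders (Most Popular,
    collective matrix factorization with side information, and the
    Offsets model for cold-start scoring) by alternating least squares;
    combines them into a weighted hybrid; and evaluates with top-K
    ranking metrics (Recall@K, Precision@K, Hit@K, NDCG@K), average
    precision and tie-corrected AUROC with macro/micro averaging, plus
    rater-agreement summaries including Fleiss' kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    arrow,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
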