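Package: slconnect
Title: Connectivity-First Prediction of Synthetic Lethality from CRISPR
    Double-Knockout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step prediction of synthetic-lethal (SL) gene pairs in an
    individual cancer cell line. Step one regresses each gene's SL
    connectivity (its number of SL partners in a labeled double-knockout
    screen) from multi-omics features and biological network views using a
    multilayer encoder (gene encoder, multiview graph encoder, transformer
    encoder, MLP head). Step two maps a pair's predicted connectivities to
    an SL probability with a logistic classifier. Includes readers for
    screen, feature, network and pathway tables; a scale-free synthetic
    benchmark generator; nonoverlap-split evaluation with AUPR, AUC-ROC and
    Precision@k; an ablation harness; and double-knockout screen analytics
    (SL rates, chi-square screen comparison, pathway-stratified reports,
    hub genes, connectivity correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    glmnet,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
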