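Package: alpcascade
Title: Hierarchical Climate-Vegetation-Habitat Cascade Models for Alpine Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hierarchical species-distribution-model cascade for alpine
    ecosystems: bioclimatic indices (warmth index, coldest-month minimum
    temperature, summer precipitation, and maximum snow-water equivalent from
    a degree-day snowpack simulation), delta-method downscaling of general
    circulation model anomalies, an additive logistic model of alpine
    vegetation-zone occurrence, random-forest regression of vegetation
    community area fractions with permutation importance, a territory
    occurrence model with a survey-effort offset and Akaike-weight variable
    importance, and multi-scenario ensemble projection of future potential
    habitat. Includes a synthetic-landscape generator with known generative
    truth for end-to-end validation, plus ROC/AUC thresholding at fixed
    sensitivity and bootstrap validation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    mgcv,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'alpcascade-package.R'
    'grid-methods.R'
    'climate.R'
    'metrics.R'
    'vegetation-models.R'
    'habitat-model.R'
    'projection.R'
    'pipeline.R'
    'terrain.R'
    'synthetic.R'
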