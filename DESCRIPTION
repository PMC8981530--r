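Package: statincost
Title: Cost-Minimisation Analysis of Statin Prescribing in Primary Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drug-utilisation and cost-minimisation analysis of statin
    prescribing in primary care. Implements defined-daily-dose (DDD) standardised
    acquisition costing from annual price/quantity tables, therapeutic dose
    substitution onto a policy comparator via LDL-cholesterol-reduction intensity
    bands, two counterfactual cost-savings scenarios (first 28 days of new
    treatment episodes, and all prescription-days for all patients), initiation
    market-share and practice-heterogeneity quintile analyses, and a seeded
    synthetic prescription-cohort and price-series generator with multinomial-logit
    prescriber choice for end-to-end testing without access to confidential
    primary-care extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, tools, yaml
Suggests: testthat (>= 3.0.0), ggplot2, withr, optparse, jsonlite
Config/testthat/edition: 3
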