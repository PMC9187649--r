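Package: resmon
Title: Pesticide Residue Monitoring Statistics and Dietary Risk Assessment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for analysing pesticide residue monitoring campaigns on
    food commodities: resolution of maximum residue limits (MRLs) under a
    positive-list default, residue and sample compliance classification,
    occurrence and incidence summary tables, deterministic acute and chronic
    dietary exposure assessment (ESTI, EDI, acute and chronic hazard
    quotients, cumulative hazard index), analytical method-validation
    statistics (LOD, LOQ, recovery, precision, linearity), and seeded
    generators for synthetic monitoring datasets including a deterministic
    reconstruction of a published reference survey from its marginal summary
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
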