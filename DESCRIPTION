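Package: craniocurve
Title: Outline-Based Quantification and Classification of Craniosynostosis Skull Shapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cranial vault shape from 3-D head surfaces using an
    outline-based polar curve. A cutting plane is defined from external
    anatomical landmarks (left/right exocanthion and one porion), the head
    surface is sliced 4 cm above that plane, and the resulting closed skull
    outline is converted to a size-normalized 360-degree radius-versus-angle
    curve starting at the occiput. From the curve the package extracts
    forehead, occiput and side extrema and derived length/width, forehead
    width and asymmetry indices, and classifies the common single-suture
    craniosynostosis phenotypes (scaphocephaly, trigonocephaly,
    brachycephaly, right- and left-sided anterior plagiocephaly) against
    controls. Includes landmark-reliability statistics (ICC(2,1)),
    group-comparison statistics (one-way ANOVA, Levene's test, Games-Howell
    post hoc with Bonferroni correction), and a seeded superellipsoid head
    phantom generator for end-to-end testing without CT data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
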