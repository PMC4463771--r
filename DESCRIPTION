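Package: milkLipidomics
Title: Shotgun Lipidomics of Milk by Precursor-Stepped MS/MS and GC-FAME Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identification and internal-standard quantification of molecular
    lipid species from data-independent MS/MS experiments acquired in 1-amu
    precursor steps (the MS/MS^ALL scheme), aimed at milk and milk-product
    lipidomes. Implements a shorthand lipid nomenclature parser, elemental
    composition assembly and monoisotopic m/z arithmetic for triacylglycerols,
    glycerophospholipids and sphingomyelin, class- and polarity-specific
    fragment prediction (neutral losses of fatty acyls from ammoniated TAG,
    fatty acyl carboxylate anions, headgroup fragments), fragment matching and
    species identification, quantification to pmol and mol% against spiked
    internal standards, per-species fatty acid index and unsaturation index
    statistics for TAG composites, GC-FAME calibration-curve profiling with
    one-way ANOVA and Fisher's LSD group comparison, and a synthetic lipidome
    generator emulating human milk, cow milk and a phospholipid-enriched
    formula for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'milkLipidomics-package.R'
    'AllClasses.R'
    'annotation.R'
    'mass.R'
    'fragments.R'
    'spectra.R'
    'identify.R'
    'quantify.R'
    'gc.R'
    'simulate.R'
    'pipeline.R'
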