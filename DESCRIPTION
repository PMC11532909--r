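Package: denovoeval
Title: Accuracy Metrics and Target-Decoy FDR Estimation for De Novo
    Peptide Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Evaluation toolkit for de novo peptide sequencing results
    from tandem mass spectrometry. Computes fragment-ion, amino-acid and
    peptide accuracy of de novo peptide-spectrum matches against
    database-search ground truth; generates decoy spectra by peak removal
    and noise-peak injection (random or intensity/peptide-mass guided);
    estimates the false discovery rate of de novo peptide-spectrum
    matches by target-decoy competition and validates it against a
    fragment-ion-coverage true FDR; and simulates mutated-peptide
    benchmarks with an in-silico b/y spectrum generator and a
    configurable mock sequencing engine, so the whole framework is
    exercisable offline. Reads and writes Mascot Generic Format (MGF)
    spectra and delimited peptide-spectrum-match tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
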