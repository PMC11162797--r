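Package: primext
Title: Kinetics and LC-MS Analysis of Non-Templated Primer Extension with
    Mixed-Sugar Activated Nucleotides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of non-templated (template-free)
    primer extension chemistry with 2-aminoimidazole-activated ribo-, arabino-
    and threo-nucleotides. Provides a monoisotopic mass engine for chimeric
    RNA/ANA/TNA/DNA oligonucleotides including uniform 13C/15N isotope labels,
    negative-mode m/z and sodium-adduct arithmetic; a deterministic mass-action
    simulator of the activation-chemistry reaction network (imidazolium-bridged
    dinucleotide formation, reversal, hydrolysis and primer extension);
    pseudo-first-order rate estimation from gel-band time courses and decay
    fitting for NMR-derived concentration series; matching of deconvoluted
    LC-MS compound lists to enumerated candidate extension products with
    normalized incorporation percentages and internal-versus-terminal hydroxyl
    reactivity deconvolution; a Markov chain-growth competition model with
    terminal-sugar-dependent chain termination; and seeded synthetic-data
    generators emulating all three measurement types for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
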