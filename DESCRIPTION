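Package: polystab
Title: Polygenic Trait Dynamics Under Stabilizing Selection with Unequal Allelic Effects
Version: 0.1.0
Authors@R: person("polystab", "maintainers", email = "polystab@example.org", role = c("aut", "cre"))
Description: Deterministic multilocus theory for a polygenic trait under
    stabilizing selection and symmetric recurrent mutation when allelic
    effects differ between loci. Provides the exact per-generation
    allele-frequency recursion (infinite population, linkage
    equilibrium), closed-form stationary genetic variance for
    gamma-distributed effect sizes including its decomposition into
    small- and large-effect contributions, and analytic approximations
    for the response of the trait mean and allele frequencies after a
    sudden shift of the phenotypic optimum: the constant-variance
    directional phase, the post-crossover stabilizing phase, and the
    single-large-locus sweep approximation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
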