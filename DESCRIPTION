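Package: calwave
Title: Fire-Diffuse-Fire Calcium Waves and Their Grover-Search Parameterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates IP3-receptor-mediated calcium-induced calcium release as
    a one-dimensional fire-diffuse-fire reaction-diffusion system, classifies
    wave fronts into saltatory and continuous regimes through the dimensionless
    parameters Gamma and beta, evaluates IP3 receptor open-channel probability
    and flux-based release balances, and maps the resulting parameter space
    onto a Grover amplitude-amplification search register so that the quadratic
    correspondence between continuous-wave velocity scaling (v ~ sqrt(D)) and
    O(sqrt(N)) quantum search can be verified numerically. Includes a dense
    statevector simulator for Grover's algorithm, Bell-state superdense coding,
    and an end-to-end pipeline producing tidy tables and plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
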