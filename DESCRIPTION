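Package: doralisa
Title: Simulating the Development of Relational Learning and Analogical
    Reasoning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A symbolic-connectionist simulator of how structured relational
    representations are discovered from unstructured feature vectors and then
    used to solve generative A:B::C:D geometric analogies.  The package
    implements the DORA/LISA family of mechanisms: a layered token hierarchy
    over a shared semantic pool, asynchronous role-filler binding, Hebbian
    predicate discovery by comparison, analogical mapping between driver and
    recipient banks, and self-supervised inference of the missing D term.
    A single top-down lateral-inhibition parameter controls every competitive
    process; varying it across simulated individuals reproduces the
    non-analogical, transitional and analogical learning trajectories
    observed in longitudinal studies of children's geometric analogy solving,
    together with their characteristic error profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
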