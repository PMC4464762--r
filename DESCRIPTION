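Package: CircuitDesign
Title: Two-Step Design of Functional Gene Circuits from Boolean Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing gene regulatory circuits that execute a target
    dynamic function. Starting from a discrete 0/1 trajectory of a signed
    Boolean network under a dominant-inhibition update rule, the package
    reverse-engineers every network topology consistent with the trajectory,
    extracts the minimal (fewest-edge) networks, and scores candidate
    topologies by continuous Hill-kinetics simulation: the Q value (fraction
    of Latin-hypercube-sampled kinetic parameter sets producing a successful
    response) and the continuous basin size (number of perturbed initial
    conditions relaxing back to the normal state). Score distributions of
    network classes are compared by Jensen-Shannon divergence with a
    permutation test, and networks are ranked by robustness. The Escherichia
    coli SOS DNA-damage response ships as a validated worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, utils, deSolve, lhs, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
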