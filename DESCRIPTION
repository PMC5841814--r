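Package: tripsyn
Title: Tripartite-Synapse Simulator of Opioid-Induced Hippocampal LTP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Biophysical simulator of a hippocampal CA3-CA1 tripartite
    synapse under mu-opioid receptor activation. Couples two presynaptic
    Hodgkin-Huxley neurons (a CA3 pyramidal bouton and a GABAergic
    interneuron with a GPCR/G-protein chain that drives N-type calcium
    channels into a reluctant state), stochastic glutamate release from a
    five-site calcium sensor, an astrocyte with IP3/calcium dynamics and
    threshold-gated gliotransmission, and a postsynaptic spine with
    morphine-modulated NMDA receptors, a CaMKII/PP1 phosphorylation ladder,
    AMPA-receptor conductance plasticity and a nitric-oxide feedback
    signal. Ships the thirteen intervention scenarios used to compare
    monitoring factors (synaptic glutamate, gliotransmitter, phosphorylated
    CaMKII, AMPAR conductance) between normal and pathological conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
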