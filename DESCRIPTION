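Package: synaptoloc
Title: Synapse Counting by 3D Puncta Colocalization in Multichannel
    Fluorescence Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs a dye-filled neuron from the fill channel of a
    multichannel 3D fluorescence stack and counts and locates its putative
    excitatory and inhibitory synaptic inputs by distance-thresholded
    colocalization of pre- and post-synaptic immunolabel puncta. Provides
    neuron surface segmentation and generalized-cylinder filament tracing,
    role-based channel masking, scale-matched 3D spot detection with
    depth-dependent background correction, anisotropy-aware spot-to-surface
    and spot-to-spot colocalization, compartment count tables, antibody
    penetration depth QC, synapse density conversion, a sliding-template
    synaptic current detector with kinetics and reversal-potential analysis,
    and a ground-truth phantom generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
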