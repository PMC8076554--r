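Package: activevision
Title: A Generative Model of Active Vision: Scene Rendering, Saccades,
    and Salience
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale simulator of active vision built around an
    explicit generative model. Scenes are assembled by recursive affine
    transformation (scale, rotate, translate) of triangulated sphere
    primitives into objects and rooms drawn from a categorical room
    prior. Binocular retinal images are produced by single-bounce ray
    casting with Blinn-Phong shading (ambient, diffuse, specular),
    shadowing, retinal inversion, and a low-pass blur implemented in the
    discrete cosine transform domain. Saccadic eye movements are
    simulated as a damped second-order plant relaxing to an equilibrium
    point, emitting II (position) and Ia (velocity) proprioceptive
    afferents for each eye. Candidate fixations are scored by expected
    information gain (predictive entropy minus expected ambiguity), and
    beliefs over rooms are updated by exact Bayesian inference on
    rendered observations. Includes lesion modes reproducing monocular
    blindness, homonymous hemianopia, and object agnosia.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
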