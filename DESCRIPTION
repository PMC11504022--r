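Package: cmbscreen
Title: Two-Stage Cerebral Microbleed Screening on Susceptibility-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully offline implementation of a two-stage
    cerebral microbleed (CMB) screening pipeline for susceptibility-weighted
    MRI (SWI) slice stacks. Stage one is a lightweight anchor-free
    single-stage detector with a saliency multi-head attention block and a
    small-object bounding-box regression loss built on the normalized
    Wasserstein distance (NWD) mixed with CIoU. Stage two is a multimodal
    image-plus-text classifier that fuses 3D crops spanning adjacent SWI
    slices and the matching phase slice with encoded clinical text prompts
    (age, gender, box geometry, slice adjacency) to reject CMB mimics such
    as calcifications and vessels. The package includes region- and
    patient-level evaluation metrics (sensitivity, specificity, precision,
    mAP, false positives per patient, patient-level accuracy), a closed-form
    inference-time model, a seeded synthetic SWI/phase phantom generator so
    every stage is trainable and testable without patient data, and readers
    and writers for PNG/NIfTI stacks and YOLO/COCO labels. Networks run on a
    small reverse-mode automatic-differentiation engine included in the
    package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    png,
    RNifti,
    yaml,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
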