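Package: lapcensor
Title: Inside-Outside Frame Classification and Censoring for Laparoscopic Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anonymizing laparoscopic surgery video by detecting and
    censoring frames recorded outside the abdomen. Frames are labelled with a
    five-way taxonomy (abdominal cavity, trocar, outside operation site,
    outside for cleaning, translucent trocar) that collapses onto a binary
    inside/outside outcome. A sequence classifier (frozen convolutional
    feature extractor, fully connected layer, stateless LSTM, focal loss)
    is trained with stratified by-video cross-validation; per-frame
    predictions are temporally smoothed, expanded to native frame rate and
    used to black out or blur privacy-critical footage. A seeded synthetic
    video generator emulates the class imbalance and segment structure of
    real laparoscopy so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
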