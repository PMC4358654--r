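Package: u3dio
Title: Write and Inspect Universal 3D (ECMA-363) Files for Interactive 3D PDF Figures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts point clouds, polyline sets and triangle meshes --
    supplied as character-separated text files, Wavefront OBJ or ASCII PLY, or
    built programmatically -- into Universal 3D (ECMA-363) files with
    hierarchical object trees, shared geometry resources, per-object colour and
    transparency, and file metadata. The resulting files are suitable for
    embedding into PDF documents as interactive 3D figures. Includes a
    structural U3D reader used as a round-trip oracle, a declarative XML-like
    object-specification language, a tabular marker-list importer with
    configurable delimiters, decimal separators and row filters, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
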