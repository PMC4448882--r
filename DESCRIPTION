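Package: microrefine
Title: Small-Molecule Crystallographic Least-Squares Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A least-squares refinement engine for small-molecule X-ray
    crystal structures. Computes complex structure factors with isotropic
    and anisotropic displacement parameters and with non-atomic "special
    shape" scattering models (spherical shell, line, torus) for severely
    disordered groups; supports geometric (DISTANCE/ANGLE/SAME) and
    displacement (SIMU/DELU rigid-bond) restraints including one-sided
    asymmetric restraints, riding hydrogens, and a per-reflection complex
    disordered-solvent contribution added to the calculated structure
    factors. The normal equations are accumulated in batches in double
    precision, restraints are accumulated one by one as sparse rank-one
    updates, and the system is diagonally preconditioned to unit diagonal
    before an LDL-transpose solve, with an eigenvalue-filtering
    pseudo-inverse fallback and multicollinearity diagnostics. Includes
    readers and writers for SHELX-style HKLF 4 reflection files, a minimal
    CIF dialect, SQUEEZE-style .fab solvent files and a plain-text
    restraint grammar, plus synthetic fixture generators so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
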