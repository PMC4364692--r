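Package: helixweaver
Title: Screw-Transform Analysis and Construction of Filamentous Protein
    Assemblies
Version: 0.1.0
Authors@R: person("helixweaver", "maintainers", role = c("aut", "cre"),
    email = "maintainers@helixweaver.invalid")
Description: Characterizes, classifies and constructs filamentous and cyclic
    protein assemblies from pairwise monomer-monomer binding geometries.
    Extracts the screw transformation (axis, rotation angle, axial
    translation) relating two copies of a monomer and derives global helical
    parameters (pitch, monomers per turn, handedness); builds regular,
    mixed-mode, curved-axis and supercoiled filament models of arbitrary
    length; performs coarse-grained rigid-body self-docking with a reduced
    6-8 van der Waals plus screened-Coulomb force field; classifies binding
    geometries as filament, cyclic, near-cyclic or near-helical and adjusts
    near-cyclic geometries to exact ring symmetry; explores binding-mode
    families with contact-constrained Metropolis Monte Carlo; and computes
    interface metrics (native-contact fractions, interface RMSD, buried
    surface area with region decomposition, groove-width profiles).
    Includes a deterministic synthetic-structure generator so the whole
    pipeline is testable without external downloads, with RecA-type
    recombinase filaments as the motivating system.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
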