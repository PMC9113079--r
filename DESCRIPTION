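Package: stenoflow
Title: Reduced-Order Haemodynamics and Virtual Fractional Flow Reserve of
    Idealized Coronary Stenoses
Version: 0.1.0
Authors@R:
    person("stenoflow", "developers", email = "stenoflow@example.org",
           role = c("aut", "cre"))
Description: Parametric construction of idealized stenosed coronary artery
    geometries (concentric/eccentric cross-sections, rounded/rectangular
    profiles, focal/uniform tapers, serial lesions, one-junction
    bifurcations sized by Murray, Finet or Huo-Kassab diameter laws) and a
    reduced-order steady haemodynamic solver that couples a
    Poiseuille-plus-expansion trans-lesion pressure-drop model to
    microvascular-resistance outlet boundaries to compute virtual
    fractional flow reserve (vFFR). Includes a study pipeline that
    enumerates the full lesion-archetype sweep, classifies physiological
    significance against the 0.80 ischaemic threshold, and writes
    per-table results, plus a command-line interface, JSON configuration,
    a clinical colour scale, and STL/VTK surface export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
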