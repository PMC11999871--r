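Package: cryptmorph
Title: Mechanochemical Bistability of Intestinal Organoid Crypt Morphogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-region spherical-cap model of intestinal organoid
    morphogenesis in which crypt shape is controlled by apicobasal
    differential tension and the lumen volume, with a curvature-dependent
    mechanosensitive feedback on actomyosin tension. Provides the analytic
    large-volume energy landscape with regime classification and bistable
    windows, a finite-lumen-volume two-cap equilibrium model with
    incompressible cells and thickness-curvature coupling, quasistatic
    continuation along volume and tension paths (hysteresis, snap-through,
    experimental scenario emulation), morphometric estimators (three-point
    opening angles, degree of crypt opening, myosin-intensity tension
    asymmetry, ablation-based lumen-state inference), power-law and
    forward-model parameter fitting, and synthetic-data generators for all
    of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
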