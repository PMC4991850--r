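Package: beescape
Title: Energetics-Based Honeybee Nectar Foraging and Landscape-Scale
    Pesticide Exposure Dilution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic single-day simulator of honeybee nectar foraging in
    heterogeneous landscapes. Per-trip energetics (Holling type-II flower
    visitation, central-place travel costs, net energetic efficiency) drive
    resource-patch choice under two colony-behaviour models: a single-optimal
    patch per hour, and recruitment-limited exploitation of several patches
    simultaneously, with hourly flower-density depletion, competition and
    renewal. Foraging outcomes are converted into sugar-based pesticide
    concentrations at the hive entrance and dilution factors relative to a
    treated reference crop. Includes a seeded synthetic landscape generator,
    GeoJSON/WKT landscape readers, hive-site enumeration on a grid, three
    mitigation scenarios (alternative untreated fields, in-field flower
    strips, off-field habitats), and Monte-Carlo assessment sweeps summarised
    by dilution-factor percentiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
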