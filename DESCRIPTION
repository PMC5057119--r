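Package: nephrogrowth
Title: Growth Estimation for Norway Lobster from Tag-Recapture and
    Length-Frequency Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Length-based growth analysis for Nephrops norvegicus (Norway
    lobster) and similar moulting crustaceans. Estimates the von Bertalanffy
    asymptotic length from catch length-frequency data with the
    Powell-Wetherall plot, and the growth constant k from tag-recapture
    increments with a "forced" Gulland-Holt regression through a fixed
    asymptotic length. Includes moult-frequency classification from increment
    distributions, captive moult detection, size-class increment and weight
    tables, carapace-length to total-length and weight conversions, and an
    individual-based simulator of stepped (moult-wise) growth, steady-state
    catch samples and captive monitoring series for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
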