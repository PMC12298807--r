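Package: tepcap
Title: Capacity and Cost Planning for Tele-Emergency Physician Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planning toolkit for regional tele-emergency physician (TEP)
    services. Models TEP demand as an M/M/k queue (infinite buffer, FIFO)
    with closed-form Erlang B/C performance analysis, cross-validates the
    analytic results with a discrete-event simulator that also covers
    non-exponential service (M/G/k), accounts for annual operating costs
    with fixed, jump-fixed and per-case variable components, and compares
    decentralized (one TEP unit per district) against centralized (one
    shared TEP center) deployment scenarios. Includes a seeded generator
    of synthetic TEP call logs with Poisson arrivals, configurable service
    durations and a Bernoulli case mix, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
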