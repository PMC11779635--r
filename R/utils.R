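# Internal helpers: seeded evaluation and classed conditions.

withSeed <- function(seed, code) {
    if (is.null(seed) || is.na(seed)) return(code)
    withr::with_seed(as.integer(seed), code)
}

# Simulation failures that a caller may retry (e.g. lineage extinction).
simFailure <- function(message, class = "matrikin_sim_failure") {
    structure(class = c(class, "matrikin_sim_failure", "error", "condition"),
              list(message = message, call = sys.call(-1)))
}

# Malformed input data.
formatError <- function(message) {
    structure(class = c("matrikin_format_error", "error", "condition"),
              list(message = message, call = sys.call(-1)))
}

# Unordered pair key "a|b" with a <= b lexicographically.
pairKey <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "|")
}
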