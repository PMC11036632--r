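# Shared fixtures: the worked 4x4 similarity matrix (fillers
# PercentageAffected:16, PercentageAffected:8, TimePoint:"week 24",
# TimePoint:"week 12"), tiny schemas, and a small generated corpus.

table3_qmat <- function() {
  q <- matrix(c(NA, 0.1, 0.7, 0.4,
                0.1, NA, 0.3, 0.8,
                0.7, 0.3, NA, 0.2,
                0.4, 0.8, 0.2, NA), 4, 4, byrow = TRUE)
  dimnames(q) <- list(c("16", "8", "week 24", "week 12"),
                      c("16", "8", "week 24", "week 12"))
  q
}

# Minimal one-template schema: root "Medication" with one textual slot.
tiny_schema_1 <- function() {
  pico_schema(list(
    list(name = "Medication",
         slots = list(list(name = "Drug", kind = "textual")))
  ), root = "Medication")
}

# Two templates: root holds one textual slot and one template slot.
tiny_schema_2 <- function() {
  pico_schema(list(
    list(name = "Trial",
         slots = list(list(name = "Name", kind = "textual"),
                      list(name = "hasDose", kind = "template",
                           child = "Dose"))),
    list(name = "Dose",
         slots = list(list(name = "Amount", kind = "textual")))
  ), root = "Trial")
}

small_corpus <- function(n = 10, seed = 42) {
  generate_corpus(fixture_config(n, seed = seed))
}
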