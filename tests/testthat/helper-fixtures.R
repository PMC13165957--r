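# Shared fixtures: tiny geometric instances and file builders.

# n uniform points in a width x height workspace, fixed seed.
random_points <- function(n, seed, width = 640, height = 640) {
  withr::with_seed(seed, data.frame(x = runif(n, 0, width),
                                    y = runif(n, 0, height)))
}

unit_square <- function() data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))

# visiting order 1-2-3-4 crosses itself on the unit square
crossing_square <- function() data.frame(x = c(0, 1, 1, 0), y = c(0, 1, 0, 1))

write_tmp_labels <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

write_tmp_json <- function(doc) {
  f <- withr::local_tempfile(fileext = ".json",
                             .local_envir = parent.frame())
  jsonlite::write_json(doc, f, auto_unbox = TRUE, digits = NA)
  f
}

# independent transcription of the planner-selection pseudocode, used as the
# oracle for the decision-tree truth table
reference_gate <- function(n, c, rho, category) {
  if (n < 3) return("reciprocating")
  if (n > 20) return("genetic")
  initial <- if (c <= 0.4) "reciprocating" else "genetic"
  if (category == "bud" && rho > 0.5) "genetic" else initial
}
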