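# Shared fixtures, built in code.

# A minimal two-knot reference: L = 1, M rising 10 -> 12, S = 0.1.
tiny_ref <- function(measure = "weight", sex = "male", label = "standard") {
  lms_reference(age = c(1, 2), L = c(1, 1), M = c(10, 12), S = c(0.1, 0.1),
                measure = measure, sex = sex, label = label)
}

# Write a delimited reference file and return its path.
write_ref_file <- function(lines, sep = ",") {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Default synthetic reference pair used across pipeline tests.
default_pair <- function(delta = c(weight = -1, height = -1.2, bmi = NA)) {
  make_reference_pair(make_base_reference(), delta = delta)
}

# The published three-band contingency counts used as an arithmetic fixture
# (standard vs specialized chart; bands under / norm / over).
published_counts <- function() {
  list(weight = cbind(standard = c(108, 280, 13), specialized = c(23, 350, 19)),
       height = cbind(standard = c(141, 246, 14), specialized = c(90, 288, 14)),
       bmi    = cbind(standard = c(83, 290, 28),  specialized = c(76, 306, 7)))
}
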