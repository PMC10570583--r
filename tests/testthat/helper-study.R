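# Shared fixtures: the packaged case study and the printed comparison
# matrices it should reproduce.

us_config <- function(...) {
  fx <- us2019_fixture()
  study_config(fx$schema, fx$evidence, fx$hierarchy, ...)
}

# printed pairwise matrices of the case study
printed_criteria_pcm <- matrix(
  c(1, 1 / 4, 1 / 5,
    4, 1, 1,
    5, 1, 1), 3, byrow = TRUE,
  dimnames = list(c("C1", "C2", "C3"), c("C1", "C2", "C3")))

printed_env_pcm <- matrix(
  c(1, 1 / 3, 1 / 5, 1 / 3,
    3, 1, 1 / 2, 1,
    5, 2, 1, 2,
    3, 1, 1 / 2, 1), 4, byrow = TRUE,
  dimnames = list(paste0("R", 1:4), paste0("R", 1:4)))

printed_state_pcm <- matrix(
  c(1, 9,
    1 / 9, 1), 2, byrow = TRUE,
  dimnames = list(c("R5", "R6"), c("R5", "R6")))

printed_behavior_pcm <- matrix(
  c(1, 2, 2,
    1 / 2, 1, 1 / 2,
    1 / 2, 2, 1), 3, byrow = TRUE,
  dimnames = list(paste0("R", 7:9), paste0("R", 7:9)))

# printed per-factor importance scores (percent)
printed_scores <- list(
  environment = c(R1 = 8.4, R2 = 22.6, R3 = 40.8, R4 = 25.3),
  driver_state = c(R5 = 18.2, R6 = 2.0),
  driver_behavior = c(R7 = 17.9, R8 = 8.8, R9 = 12.0))
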