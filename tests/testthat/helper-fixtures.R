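# shared fixture builders

# random state-code vector
rand_states <- function(n) sample.int(5L, n, replace = TRUE)

# a tiny symmetric dissimilarity matrix with zero diagonal
rand_diss <- function(u, scale = 10) {
  m <- matrix(0, u, u)
  m[upper.tri(m)] <- runif(u * (u - 1) / 2, 0, scale)
  m + t(m)
}

# records data.frame for one woman with a hand-written calendar
one_record <- function(calendar, interview_cmc = 1405,
                       birth_cmc = interview_cmc - 58 - 25 * 12,
                       case_id = "w1", weight = 1, psu = 1, stratum = 1) {
  data.frame(case_id = case_id, calendar = calendar,
             interview_cmc = interview_cmc, birth_cmc = birth_cmc,
             weight = weight, psu = psu, stratum = stratum,
             stringsAsFactors = FALSE)
}

# small generated dataset reused across clustering tests
small_gen <- function(n = 200, seed = 101, noise = 0.03, jitter = 2, ...) {
  generate(generator_config(n_women = n, seed = seed,
                            noise_sub_prob = noise, jitter_max = jitter, ...))
}

# closed-form turbulence for a spell-duration vector and DSS phi
turbulence_closed_form <- function(phi, durations) {
  m <- length(durations)
  tbar <- mean(durations)
  s2 <- mean((durations - tbar)^2)
  s2max <- (m - 1) * (tbar - 1)^2
  log2(phi * (s2max + 1) / (s2 + 1))
}
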