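# shared builders for small in-code fixtures

toy_cohort <- function() {
  new_cohort(
    data.frame(
      patient_id = c("A", "B", "C", "D"),
      stage = c("1A", "3B", "2C", "3"),
      lowest_cmc = c(0L, 3L, 1L, 0L),
      highest_cmc = c(1L, 40L, 5L, 0L),
      metastasis = c(FALSE, TRUE, TRUE, FALSE),
      event_day = c(400L, 220L, 610L, 900L),
      stringsAsFactors = FALSE
    )
  )
}

# cohort with long-format serial samples for the survival/cluster paths
serial_cohort <- function() {
  patients <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4", "P5"),
    stage = c("3A", "3B", "2B", "1B", "3C"),
    lowest_cmc = c(0L, 2L, 1L, 0L, 120L),
    highest_cmc = c(4L, 30L, 1L, 8L, 120L),
    metastasis = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    event_day = c(300L, 150L, 500L, 420L, 90L),
    stringsAsFactors = FALSE
  )
  samples <- data.frame(
    patient_id = c("P1", "P1", "P2", "P2", "P3", "P3", "P4", "P4", "P5"),
    day = c(0L, 200L, 0L, 100L, 0L, 450L, 0L, 420L, 0L),
    cmc_count = c(0L, 4L, 2L, 30L, 1L, 1L, 0L, 8L, 120L),
    stringsAsFactors = FALSE
  )
  new_cohort(patients, samples)
}

# brute-force two-sided Fisher p by direct factorial enumeration,
# independent of the hypergeometric-support implementation under test
fisher_bruteforce <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  point <- function(x) {
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(x) -
          lfactorial(r1 - x) - lfactorial(c1 - x) -
          lfactorial(r2 - c1 + x))
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  ps <- vapply(xs, point, 0)
  p_obs <- point(a)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}
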