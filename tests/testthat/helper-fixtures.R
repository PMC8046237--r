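# Shared fixtures, built in code at test time.

# A synthetic value set with all-nonpositive decrements and extra terms, for
# tests that must not depend on the packaged US tariff's exact numbers.
synthetic_value_set <- function(with_extra = TRUE) {
  eq5d_value_set(
    name = "synthetic-nonpositive",
    decrements = list(
      mobility = c("2" = -0.10, "3" = -0.30),
      self_care = c("2" = -0.08, "3" = -0.25),
      usual_activities = c("2" = -0.05, "3" = -0.15),
      pain_discomfort = c("2" = -0.12, "3" = -0.35),
      anxiety_depression = c("2" = -0.07, "3" = -0.20)
    ),
    extra_terms = if (with_extra) c(n3 = -0.05, d1 = -0.02) else numeric(0)
  )
}

# Small deterministic patient table with sub-domain scores and covariates.
tiny_records <- function(n = 8L) {
  set.seed(99)
  df <- data.frame(
    id = seq_len(n),
    epic_urinary = round(runif(n, 60, 100), 1),
    epic_bowel = round(runif(n, 70, 100), 1),
    epic_sexual = round(runif(n, 10, 90), 1),
    epic_hormonal = round(runif(n, 70, 100), 1),
    epic_uf = round(runif(n, 60, 100), 1),
    epic_ub = round(runif(n, 50, 100), 1),
    epic_uirr = round(runif(n, 60, 100), 1),
    epic_uinc = round(runif(n, 60, 100), 1),
    epic_bf = round(runif(n, 70, 100), 1),
    epic_bb = round(runif(n, 70, 100), 1),
    epic_sf = round(runif(n, 10, 90), 1),
    epic_sb = round(runif(n, 10, 100), 1),
    epic_hf = round(runif(n, 60, 100), 1),
    epic_hb = round(runif(n, 70, 100), 1),
    age = round(runif(n, 55, 78), 1),
    race_other = rbinom(n, 1, 0.2),
    zubrod = rbinom(n, 1, 0.1),
    psa_ge4 = rbinom(n, 1, 0.8)
  )
  df$eq5d <- round(runif(n, 0.4, 1), 2)
  df
}

# One-row record with every score at a given value.
flat_record <- function(score = 100, zubrod = 0, age = 66, race_other = 0,
                        psa_ge4 = 0) {
  data.frame(
    epic_urinary = score, epic_bowel = score, epic_sexual = score,
    epic_hormonal = score,
    epic_uf = score, epic_ub = score, epic_uirr = score, epic_uinc = score,
    epic_bf = score, epic_bb = score, epic_sf = score, epic_sb = score,
    epic_hf = score, epic_hb = score,
    age = age, race_other = race_other, zubrod = zubrod, psa_ge4 = psa_ge4
  )
}
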