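# Synthetic observation windows with uniform random censoring, built from a
# simulated cohort's ground truth (requires death_model = NULL so that every
# latent case has an onset age). cmax ~ 150 yields roughly 30% of cases
# censored before onset for a lognormal(log 45, 0.45) onset distribution.
censored_windows <- function(cohort, trait = 1L, cmax = 150, admin_age = 100) {
  gt <- attr(cohort, "ground_truth")
  onset <- gt$onset_age[, trait]
  latent <- gt$latent[, trait]
  n <- nrow(cohort$individuals)
  C <- runif(n, 0, cmax)
  exit <- pmin(C, admin_age)
  observed <- latent & !is.na(onset) & onset <= exit
  exit[observed] <- onset[observed]
  data.frame(person_id = cohort$individuals$person_id,
             entry_age = 0, exit_age = exit, affected = observed,
             prevalent_at_entry = FALSE, stringsAsFactors = FALSE)
}

# fully observed windows: every latent case is seen at its onset age
full_windows <- function(cohort, trait = 1L, admin_age = 110) {
  gt <- attr(cohort, "ground_truth")
  onset <- gt$onset_age[, trait]
  latent <- gt$latent[, trait]
  exit <- rep(admin_age, nrow(cohort$individuals))
  exit[latent] <- onset[latent]
  data.frame(person_id = cohort$individuals$person_id,
             entry_age = 0, exit_age = exit, affected = latent,
             prevalent_at_entry = FALSE, stringsAsFactors = FALSE)
}
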