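# Shared small fixtures, built once per test run.

fix_templates <- make_templates(n_features = 30, separation = 4, seed = 11)
fix_stations <- default_stations()
fix_models <- train_station_models(
  generate_training_cohort(
    cohort_config(n_participants = 12, n_runs = 2, n_features = 30,
                  seed = 12),
    fix_templates, fix_stations))
fix_norms <- estimate_pilot_norms(
  generate_pilot_cohort(
    cohort_config(n_participants = 10, n_runs = 4, n_features = 30,
                  seed = 13),
    fix_templates, fix_models, fix_stations))

# A deterministic hand-made questionnaire response.
make_response <- function(interp = rep(1L, 12), comp = comprehension_key(),
                          empathy = c(Arthur = 4L, Lee = 2L, Joanie = 3L,
                                      girl = 3L),
                          excluded = 12L) {
  structure(
    list(comprehension_answers = comp, interpretation_answers = interp,
         excluded_item = excluded, empathy = empathy),
    class = "questionnaire_response"
  )
}
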