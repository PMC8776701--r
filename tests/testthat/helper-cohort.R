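# cohorts are expensive to generate; cache them once per test run.
# seeds are fixed design choices, not tuned.

.rpv_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .rpv_cache))
    assign(key, force(expr), envir = .rpv_cache)
  get(key, envir = .rpv_cache)
}

# the 100-patient cohort with logistic labels loading on fV20 (the
# generator's default strong-effect demonstration model)
big_cohort <- function() {
  cached("cohort100", make_cohort(cohort_spec(100, seed = 42)))
}

# 50-repeat experiment on the big cohort's true labels
signal_experiment <- function() {
  cached("exp_signal",
         run_experiment(big_cohort()$table,
                        scheme = split_scheme(n_repeats = 50, seed = 42)))
}

# 50-repeat experiment with labels permuted (seeded) on the same features
null_experiment <- function() {
  cached("exp_null", {
    ft <- big_cohort()$table
    set.seed(4242)
    ft_null <- feature_table(ft$features, sample(ft$label), ft$patient_id)
    run_experiment(ft_null, scheme = split_scheme(n_repeats = 50, seed = 42))
  })
}

small_cohort <- function() {
  cached("cohort30", make_cohort(cohort_spec(30, seed = 7)))
}
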