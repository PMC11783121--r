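# shared fixtures: models and small file fixtures built in code

# calibrated package defaults
default_model <- function() pk_model()

# model with the example parameterisation used by several worked examples
# (typical Css 26 nM, activity coefficient 1.8, omega 0.25, sigma 0.20)
example_model <- function() {
  pk_model(tvc20 = 26, theta_as = 1.8, omega = 0.25, sigma = 0.20)
}

write_patients_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

reference_patient <- function(id = "P1", diplotype = "*1/*1") {
  data.frame(patient_id = id, age = 57, height = 168,
             weight = 26.2 * 1.68^2, diplotype = diplotype,
             stringsAsFactors = FALSE)
}

# random 2x2 tables with positive margins
random_tables <- function(n, seed, lambda_max = 30) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      t <- matrix(rpois(4, sample(2:lambda_max, 1)), 2, 2)
      if (all(rowSums(t) > 0) && all(colSums(t) > 0)) return(t)
    }
  })
}
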