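# Fixtures built in code.

# Two missingness blocks: samples A,B observe {f1,f2}; C,D observe {f2,f3}.
# The intersection closure has exactly three feature sets:
# {f1,f2} x {A,B}, {f2,f3} x {C,D}, {f2} x {A,B,C,D}.
toy_two_block <- function() {
  v <- matrix(c(1, 2, NA,
                3, 4, NA,
                NA, 5, 6,
                NA, 7, 8), nrow = 4, byrow = TRUE,
              dimnames = list(c("A", "B", "C", "D"), c("f1", "f2", "f3")))
  ml_dataset(v, outcome = c("case", "control", "case", "control"),
             positive_class = "case")
}

complete_toy <- function(n = 12, p = 4, seed = 1) {
  set.seed(seed)
  ml_dataset(matrix(rnorm(n * p), n, p),
             outcome = rep(c("case", "control"), length.out = n),
             positive_class = "case")
}

random_missing_dataset <- function(n, p, miss_rate, seed) {
  set.seed(seed)
  v <- matrix(rnorm(n * p), n, p)
  v[matrix(runif(n * p) < miss_rate, n, p)] <- NA
  ml_dataset(v, outcome = rep(c("case", "control"), length.out = n),
             positive_class = "case")
}

quick_cv <- function(folds = 3, repeats = 1) cv_plan(folds, repeats)

subset_dataset_for_test <- function(d, idx)
  tabml:::subset_dataset(d, samples = idx)
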