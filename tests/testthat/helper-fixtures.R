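# Shared fixture builders; everything is generated in code.

toy_dataset <- function() {
  desc <- variable_descriptors(c("TD1", "UD1"),
                               role = c("input", "output"),
                               care_group = c("D", "D"),
                               measure = c("T", "U"))
  ecosystem_dataset(matrix(c(1, 3, 2, 4), 2, 2,
                           dimnames = list(c("A", "B"),
                                           c("TD1", "UD1"))),
                    desc)
}

small_ecosystem <- function(seed = 11, n_dmu = 19) {
  generate_ecosystem(fixture_config(n_dmu = n_dmu), seed = seed)
}

# Frequencies engineered so that descending accumulation crosses the
# 0.8 threshold at 3 intervals with an accumulated probability of 0.88,
# over 5 populated intervals (the reference worked-example shape).
example_e_freq <- function() {
  f <- numeric(22)
  f[c(10, 12, 14, 16, 18)] <- c(0.05, 0.07, 0.20, 0.24, 0.44)
  f
}

# Independent multiplier-form VRS oracle (dual program), solved with
# boot::simplex: max u'y_k + u0  s.t.  v'x_k = 1, u'Y - v'X + u0 <= 0.
# Input orientation; free u0 split into u0p - u0m.
multiplier_vrs_input <- function(X, Y, k) {
  m <- ncol(X); s <- ncol(Y)
  a <- c(rep(0, m), Y[k, ], 1, -1)
  A1 <- cbind(-X, Y, 1, -1)
  b1 <- rep(0, nrow(X))
  A3 <- matrix(c(X[k, ], rep(0, s + 2)), 1)
  r <- boot::simplex(a, A1 = A1, b1 = b1, A3 = A3, b3 = 1, maxi = TRUE)
  unname(r$value)
}
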