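# Independent oracles, kept deliberately naive and separate from the
# implementations they check.

# Fisher two-sided p by direct enumeration of all tables sharing the
# observed margins, with probabilities from binomial coefficients.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  prob <- vapply(lo:hi, function(x)
    choose(r1, x) * choose(r2, c1 - x), numeric(1)) / choose(n, c1)
  obs <- prob[a - lo + 1]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# Pearson chi-squared from expected cells, optional Yates clamp.
chi2_expected_oracle <- function(a, b, c, d, correct = FALSE) {
  O <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  dev <- abs(O - E)
  if (correct) dev <- pmax(dev - 0.5, 0)
  sum(dev^2 / E)
}

# BH step-up computed literally from the definition.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(sorted[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Random 2x2 tables with all margins positive.
random_tables <- function(n_tables, max_cell = 200) {
  repeat {
    tabs <- matrix(sample.int(max_cell, 4 * n_tables, replace = TRUE),
                   ncol = 4)
    ok <- rowSums(tabs[, c(1, 2), drop = FALSE]) > 0 &
      rowSums(tabs[, c(3, 4), drop = FALSE]) > 0
    if (all(ok)) return(tabs)
  }
}

# Tiny interaction table: drugs as named list of target vectors.
make_interactions <- function(targets) {
  data.frame(
    drug_id = rep(names(targets), lengths(targets)),
    drug_name = rep(names(targets), lengths(targets)),
    gene_symbol = unlist(targets, use.names = FALSE),
    source = "test", stringsAsFactors = FALSE)
}
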