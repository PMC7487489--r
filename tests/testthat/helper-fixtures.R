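# Quick expression-matrix fixture: rows of lognormal abundance with an
# optional per-feature multiplicative shift in the cancer group.
make_expr <- function(n_features = 10, n_cancer = 5, n_control = 5,
                      log2_shift = rep(0, n_features), noise_sd = 0.5,
                      base_mean = 6) {
  n <- n_cancer + n_control
  ids <- sprintf("f%03d", seq_len(n_features))
  samples <- c(sprintf("T%02d", seq_len(n_cancer)),
               sprintf("N%02d", seq_len(n_control)))
  groups <- stats::setNames(c(rep("cancer", n_cancer),
                              rep("control", n_control)), samples)
  base <- rnorm(n_features, base_mean, 1)
  logx <- outer(base, rep(0, n), `+`) +
    outer(log2_shift, as.numeric(groups == "cancer")) +
    matrix(rnorm(n_features * n, 0, noise_sd), nrow = n_features)
  m <- 2^logx
  dimnames(m) <- list(ids, samples)
  expression_matrix(m, groups)
}
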