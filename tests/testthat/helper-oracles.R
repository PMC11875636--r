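# Brute-force Shapley oracle: average marginal contribution over all d!
# feature orderings. Independent of the package's subset-weight formula.
all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))))
}

shap_oracle <- function(value, d) {
  perms <- all_perms(d)
  phi <- numeric(d)
  for (r in seq_len(nrow(perms))) {
    cur <- rep(FALSE, d)
    for (k in perms[r, ]) {
      before <- value(cur); cur[k] <- TRUE
      phi[k] <- phi[k] + value(cur) - before
    }
  }
  phi / nrow(perms)
}
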