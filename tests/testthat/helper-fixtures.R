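# shared fixture builders; everything is generated in code at test time

tiny_table <- function(values = 1:6, nf = 3, ns = 2, kind = "microbe",
                       prefix = "f") {
  m <- matrix(values, nrow = nf,
              dimnames = list(paste0(prefix, seq_len(nf)),
                              paste0("s", seq_len(ns))))
  feature_table(m, kind)
}

# write a minimal PathSeq-style score table
write_pathseq_file <- function(path, names, types, values,
                               value_col = "unambiguous") {
  df <- data.frame(tax_id = seq_along(names), taxonomy = names,
                   type = types, name = names, reads = values + 1)
  df[[value_col]] <- values
  if (value_col != "score") df$score <- values / 2
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent enumeration oracle for the two-sided Fisher point-probability
# rule: sum all hypergeometric point probabilities <= observed, over every
# table with the observed margins
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(a_range, function(a)
    choose(r1, a) * choose(n - r1, c1 - a) / choose(n, c1), 0)
  obs <- probs[match(tab[1, 1], a_range)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# classical BH step-up rejection set at level alpha
bh_stepup_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= seq_len(m) / m * alpha)
  rej <- rep(FALSE, m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# Breslow partial log-likelihood for a single covariate (used as the
# grid-search oracle for cox_ph)
breslow_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    d <- which(times == t & events == 1)
    risk <- which(times >= t)
    ll <- ll + sum(x[d]) * beta -
      length(d) * log(sum(exp(x[risk] * beta)))
  }
  ll
}
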