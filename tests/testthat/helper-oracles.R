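# independent brute-force enumeration of sense-codon -> stop single
# substitutions, written against the raw genetic-code table
brute_force_stop_gains <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases,
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$b1, grid$b2, grid$b3)
  stops <- codons[Biostrings::GENETIC_CODE[codons] == "*"]
  out <- character(0)
  for (ref in setdiff(codons, stops)) {
    for (p in 1:3) {
      for (b in bases) {
        alt <- ref
        substr(alt, p, p) <- b
        if (alt != ref && alt %in% stops) {
          out <- c(out, paste(ref, p, alt))
        }
      }
    }
  }
  sort(unique(out))
}

# independent Fisher oracle: full hypergeometric enumeration of 2x2 tables
# with fixed margins, summing probabilities <= that of the observed table
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  logp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  p_obs <- exp(logp(a))
  xs <- lo:hi
  sum(exp(logp(xs))[exp(logp(xs)) <= p_obs * (1 + 1e-7)])
}

# score-test inversion oracle for the Wilson interval: the bounds are the
# roots of (p_hat - p)^2 = z^2 p(1-p)/n
wilson_oracle <- function(k, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p_hat <- k / n
  f <- function(p) (p_hat - p)^2 - z^2 * p * (1 - p) / n
  lo <- if (k == 0) 0 else stats::uniroot(f, c(1e-12, p_hat),
                                          tol = 1e-12)$root
  hi <- if (k == n) 1 else stats::uniroot(f, c(p_hat, 1 - 1e-12),
                                          tol = 1e-12)$root
  100 * c(lo, hi)
}
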