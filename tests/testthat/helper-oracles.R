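## Independent oracles used across the suite. These deliberately avoid
## the package's code paths (and pwilcox/phyper) so that agreement is a
## two-route check, not a tautology.

## Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
## choose(nx+ny, nx) rank assignments, with the same two-sided doubling
## convention as the conventional exact test.
oracle_wilcox_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  u <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  p <- if (w_obs > mu) 2 * mean(u >= w_obs) else 2 * mean(u <= w_obs)
  min(p, 1)
}

## Upper-tail hypergeometric P(X >= k) by direct summation of the pmf
## written with choose().
oracle_hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## string reverse complement over RNA letters, written independently
oracle_rc <- function(s) {
  map <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(unname(map[strsplit(s, "", fixed = TRUE)[[1L]]])),
        collapse = "")
}

## Brute-force canonical seed-site scan: every window is compared
## directly against the explicit site-type definitions, then 8mer
## matches suppress the 7mer matches they subsume at the same locus.
oracle_seed_sites <- function(mirna, utr) {
  mirna <- chartr("Tt", "Uu", toupper(mirna))
  utr <- chartr("Tt", "Uu", toupper(utr))
  t8 <- paste0(oracle_rc(substr(mirna, 2L, 8L)), "A")   # 8mer site
  t7m8 <- oracle_rc(substr(mirna, 2L, 8L))              # 7mer-m8
  t7a1 <- paste0(oracle_rc(substr(mirna, 2L, 7L)), "A") # 7mer-A1
  L <- nchar(utr)
  hits <- list()
  for (s in seq_len(max(L - 7L, 0L))) {
    if (substr(utr, s, s + 7L) == t8) {
      hits[[length(hits) + 1L]] <- data.frame(utr_start = s,
                                              utr_end = s + 7L,
                                              site_type = "8mer")
    }
  }
  eight_starts <- vapply(hits, function(h) h$utr_start, numeric(1L))
  for (s in seq_len(max(L - 6L, 0L))) {
    if (substr(utr, s, s + 6L) == t7m8 && !(s %in% eight_starts)) {
      hits[[length(hits) + 1L]] <- data.frame(utr_start = s,
                                              utr_end = s + 6L,
                                              site_type = "7mer-m8")
    }
    if (substr(utr, s, s + 6L) == t7a1 && !((s - 1L) %in% eight_starts)) {
      hits[[length(hits) + 1L]] <- data.frame(utr_start = s,
                                              utr_end = s + 6L,
                                              site_type = "7mer-A1")
    }
  }
  if (!length(hits)) {
    return(data.frame(utr_start = integer(), utr_end = integer(),
                      site_type = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$utr_start, out$site_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## small editing matrix with named groups for unit tests
make_profile <- function(values, n_res, n_sen) {
  samples <- c(sprintf("R%02d", seq_len(n_res)),
               sprintf("S%02d", seq_len(n_sen)))
  m <- matrix(values, ncol = n_res + n_sen, byrow = TRUE,
              dimnames = list(sprintf("site%02d",
                                      seq_len(length(values) /
                                              (n_res + n_sen))),
                              samples))
  m
}

make_condition <- function(profile, n_res) {
  samples <- colnames(profile)
  condition("TST", "DrugT", samples[seq_len(n_res)],
            samples[(n_res + 1L):length(samples)])
}
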