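# Independent naive re-implementations of the stratified 2x2 machinery,
# written as plain scalar loops over direct textbook formulas. These are
# deliberately a different code path from the package's vectorized core and
# serve as oracles in the equivalence tests.

# tables: list of length-4 count vectors (case_exp, case_unexp, ctrl_exp,
# ctrl_unexp)
naive_mh_or <- function(tables) {
  num <- 0; den <- 0
  for (tb in tables) {
    a <- as.numeric(tb[1]); b <- as.numeric(tb[2])
    c <- as.numeric(tb[3]); d <- as.numeric(tb[4])
    n <- a + b + c + d
    if (n == 0) next
    num <- num + a * d / n
    den <- den + b * c / n
  }
  if (num == 0 && den == 0) return(NA_real_)
  num / den
}

naive_rbg_ci <- function(tables, level = 0.95) {
  sr <- 0; ss <- 0; t1 <- 0; t2 <- 0; t3 <- 0
  for (tb in tables) {
    a <- as.numeric(tb[1]); b <- as.numeric(tb[2])
    c <- as.numeric(tb[3]); d <- as.numeric(tb[4])
    n <- a + b + c + d
    if (n == 0) next
    P <- (a + d) / n; Q <- (b + c) / n
    R <- a * d / n; S <- b * c / n
    sr <- sr + R; ss <- ss + S
    t1 <- t1 + P * R
    t2 <- t2 + P * S + Q * R
    t3 <- t3 + Q * S
  }
  if (sr == 0 || ss == 0) return(c(NA_real_, NA_real_))
  v <- t1 / (2 * sr^2) + t2 / (2 * sr * ss) + t3 / (2 * ss^2)
  z <- qnorm(1 - (1 - level) / 2)
  or <- sr / ss
  c(exp(log(or) - z * sqrt(v)), exp(log(or) + z * sqrt(v)))
}

naive_cmh_stat <- function(tables, continuity = TRUE) {
  dev <- 0; var <- 0
  for (tb in tables) {
    a <- as.numeric(tb[1]); b <- as.numeric(tb[2])
    c <- as.numeric(tb[3]); d <- as.numeric(tb[4])
    n <- a + b + c + d
    if (n == 0) next
    n1 <- a + b; n0 <- c + d; m1 <- a + c; m0 <- b + d
    dev <- dev + a - n1 * m1 / n
    if (n >= 2) var <- var + n1 * n0 * m1 * m0 / (n^2 * (n - 1))
  }
  if (var == 0) return(list(stat = NA_real_, p = NA_real_))
  cc <- if (continuity) 0.5 else 0
  stat <- max(abs(dev) - cc, 0)^2 / var
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# random stratified table set: counts 0..200, 1-4 strata; avoids the
# fully-degenerate all-zero case
random_tables <- function(n_strata = sample(1:4, 1), max_count = 200) {
  repeat {
    tabs <- lapply(seq_len(n_strata), function(i)
      sample(0:max_count, 4, replace = TRUE))
    if (sum(unlist(tabs)) > 0) return(tabs)
  }
}

as_strat <- function(tables)
  stratified_table(do.call(rbind, tables))
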