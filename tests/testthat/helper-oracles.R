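# Independent statistical oracles, deliberately naive: exact p by
# enumerating every assignment of pooled ranks to the first sample; normal
# approximation by the textbook z formula with tie and continuity
# corrections; Kruskal-Wallis H by hand-ranked brute force.

enum_exact_p <- function(x, y, alternative = "two_sided") {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(N, n1), 2, function(s) {
    sum(seq_len(N)[s]) - n1 * (n1 + 1) / 2
  })
  switch(alternative,
         less = mean(us <= u_obs),
         greater = mean(us >= u_obs),
         two_sided = min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs))))
}

normal_approx_p <- function(x, y, continuity = TRUE) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) *
    ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- u - mu
  if (continuity) z <- z - sign(z) * 0.5
  z <- z / sqrt(sigma2)
  min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
}

kw_brute_H <- function(groups) {
  N <- sum(lengths(groups))
  r <- rank(unlist(groups))
  idx <- rep(seq_along(groups), lengths(groups))
  Rj <- tapply(r, idx, sum)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(r)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
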