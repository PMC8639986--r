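# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# brute-force mass-action equilibrium: solve 2[D] + [M] = T, K = [M]^2/[D]
# for the monomer concentration by root bracketing, then f_D = 1 - M/T
fd_mass_action <- function(total, k) {
  vapply(seq_along(total), function(i) {
    tt <- total[i]
    kk <- if (length(k) > 1) k[i] else k
    m <- uniroot(function(m) 2 * m^2 / kk + m - tt,
                 lower = 0, upper = tt, tol = 1e-14 * tt)$root
    1 - m / tt
  }, 0.0)
}

# law-of-total-variance apparent brightness for a species mixture
eps_oracle <- function(mu, s, q) q * sum(mu * s^2) / sum(mu * s)

# brute-force cumulative share of the k largest values
share_brute <- function(signal, k) {
  s <- sort(signal, decreasing = TRUE)
  sum(s[seq_len(k)]) / sum(s)
}

# textbook Pearson correlation from raw sums
cor_brute <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sd(x) * sd(y))
}

# a small tiled HDX design shared by the difference-pipeline tests:
# `block` peptides get a +shift RFU bump in condition B at t > 0
hdx_shift_design <- function(seed, shift = 0.2, back = 0.25) {
  n_res <- 60
  seqres <- paste(rep(c("G", "A", "L", "K", "E", "V"), length.out = n_res),
                  collapse = "")
  peptides <- data.frame(start = seq(1, 51, by = 5))
  peptides$end <- peptides$start + 9
  rates <- rep(0.5, n_res)
  a <- sim_hdx_peptides(seqres, rates = rates, peptides = peptides,
                        back_exchange = back, replicate_sd = 0.05,
                        seed = seed)
  b <- sim_hdx_peptides(seqres, rates = rates, peptides = peptides,
                        back_exchange = back, replicate_sd = 0.05,
                        seed = seed + 10000)
  block <- b$start >= 21 & b$end <= 40
  mx <- max_exchangeable(b$sequence)
  bump <- shift * mx * (1 - back)
  b$centroid_mass <- b$centroid_mass + ifelse(block & b$time > 0, bump, 0)
  list(a = a, b = b,
       block_ids = unique(b$peptide_id[block]))
}
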