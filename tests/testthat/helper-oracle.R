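# Brute-force oracle for the fully-within three-way RM-ANOVA: explicit
# mean subtractions over index sets, written independently of the
# package's inclusion-exclusion implementation.
brute_rm_anova3 <- function(y) {
  dn <- dim(y)
  n <- dn[1]; a <- dn[2]; b <- dn[3]; c <- dn[4]
  g <- mean(y)
  m_s <- apply(y, 1, mean); m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean); m_c <- apply(y, 4, mean)
  m_sa <- apply(y, c(1, 2), mean); m_sb <- apply(y, c(1, 3), mean)
  m_sc <- apply(y, c(1, 4), mean)
  m_ab <- apply(y, c(2, 3), mean); m_ac <- apply(y, c(2, 4), mean)
  m_bc <- apply(y, c(3, 4), mean)
  m_sab <- apply(y, c(1, 2, 3), mean); m_sac <- apply(y, c(1, 2, 4), mean)
  m_sbc <- apply(y, c(1, 3, 4), mean); m_abc <- apply(y, c(2, 3, 4), mean)

  SS <- list(
    A = n * b * c * sum((m_a - g)^2),
    B = n * a * c * sum((m_b - g)^2),
    C = n * a * b * sum((m_c - g)^2),
    AB = 0, AC = 0, BC = 0, ABC = 0,
    SA = 0, SB = 0, SC = 0, SAB = 0, SAC = 0, SBC = 0, SABC = 0)
  for (i in 1:a) for (j in 1:b)
    SS$AB <- SS$AB + n * c * (m_ab[i, j] - m_a[i] - m_b[j] + g)^2
  for (i in 1:a) for (k in 1:c)
    SS$AC <- SS$AC + n * b * (m_ac[i, k] - m_a[i] - m_c[k] + g)^2
  for (j in 1:b) for (k in 1:c)
    SS$BC <- SS$BC + n * a * (m_bc[j, k] - m_b[j] - m_c[k] + g)^2
  for (i in 1:a) for (j in 1:b) for (k in 1:c)
    SS$ABC <- SS$ABC + n * (m_abc[i, j, k] - m_ab[i, j] - m_ac[i, k] -
                              m_bc[j, k] + m_a[i] + m_b[j] + m_c[k] - g)^2
  for (s in 1:n) for (i in 1:a)
    SS$SA <- SS$SA + b * c * (m_sa[s, i] - m_s[s] - m_a[i] + g)^2
  for (s in 1:n) for (j in 1:b)
    SS$SB <- SS$SB + a * c * (m_sb[s, j] - m_s[s] - m_b[j] + g)^2
  for (s in 1:n) for (k in 1:c)
    SS$SC <- SS$SC + a * b * (m_sc[s, k] - m_s[s] - m_c[k] + g)^2
  for (s in 1:n) for (i in 1:a) for (j in 1:b)
    SS$SAB <- SS$SAB + c * (m_sab[s, i, j] - m_sa[s, i] - m_sb[s, j] -
                              m_ab[i, j] + m_s[s] + m_a[i] + m_b[j] - g)^2
  for (s in 1:n) for (i in 1:a) for (k in 1:c)
    SS$SAC <- SS$SAC + b * (m_sac[s, i, k] - m_sa[s, i] - m_sc[s, k] -
                              m_ac[i, k] + m_s[s] + m_a[i] + m_c[k] - g)^2
  for (s in 1:n) for (j in 1:b) for (k in 1:c)
    SS$SBC <- SS$SBC + a * (m_sbc[s, j, k] - m_sb[s, j] - m_sc[s, k] -
                              m_bc[j, k] + m_s[s] + m_b[j] + m_c[k] - g)^2
  for (s in 1:n) for (i in 1:a) for (j in 1:b) for (k in 1:c)
    SS$SABC <- SS$SABC +
      (y[s, i, j, k] - m_sab[s, i, j] - m_sac[s, i, k] - m_sbc[s, j, k] -
         m_abc[i, j, k] + m_sa[s, i] + m_sb[s, j] + m_sc[s, k] +
         m_ab[i, j] + m_ac[i, k] + m_bc[j, k] -
         m_s[s] - m_a[i] - m_b[j] - m_c[k] + g)^2
  SS
}

# complete factorial band-power table from a subject x hemi x state x band
# value array (dims n x 2 x 5 x 5)
table_from_array <- function(y) {
  n <- dim(y)[1]
  d <- expand.grid(subject = sprintf("s%02d", 1:n),
                   hemisphere = c("L", "R"),
                   state = c("AI", "AT", "S40", "S60", "S80"),
                   band = c("A", "B", "C", "D", "E"),
                   stringsAsFactors = FALSE)
  d$log_power <- y[cbind(match(d$subject, sprintf("s%02d", 1:n)),
                         match(d$hemisphere, c("L", "R")),
                         match(d$state, c("AI", "AT", "S40", "S60", "S80")),
                         match(d$band, c("A", "B", "C", "D", "E")))]
  d
}

# random null band-power table: subject intercepts plus iid noise
null_bp_array <- function(n = 12, subj_sd = 1, noise_sd = 1) {
  y <- array(rnorm(n * 2 * 5 * 5, sd = noise_sd), dim = c(n, 2, 5, 5))
  y + rnorm(n, sd = subj_sd)   # recycles over the first dimension
}

# amplitude of a steady sinusoid in the interior of a filtered signal
interior_peak <- function(x, fs, skip_s = 2) {
  i <- (skip_s * fs):(length(x) - skip_s * fs)
  max(abs(x[i]))
}

# small synthetic stimulated session used across artifact tests
quick_stim_cfg <- function(seed = 42, n_trials = c(S60 = 2), ...) {
  synth_config(seed = seed, n_trials = n_trials, iti_s = 2, ...)
}
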